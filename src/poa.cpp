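#include <Rcpp.h>
#include <string>
#include <vector>
#include <queue>
#include <algorithm>
using namespace Rcpp;

// A small partial-order alignment engine. Sequences are aligned one by one to
// a growing DAG (nodes = bases, edges = observed adjacencies with read
// support); consensus paths are extracted as heaviest paths by accumulated
// edge weight. A second consensus is obtained by zeroing the first path's
// edge weights and re-running the heaviest-path search, which walks the other
// side of every well-supported bubble (diploid use-case).
//
// Read-vs-graph alignment is "fitting": the read is global, the graph ends
// are free, so partial window-spanning segments only reinforce their span.

namespace {

struct Poa {
    std::vector<char> base;
    // out edges: (to, weight); kept sorted by insertion, searched linearly
    std::vector<std::vector<std::pair<int, double> > > out;
    int match, mismatch, gap;

    Poa(int m, int mm, int g) : match(m), mismatch(mm), gap(g) {}

    int add_node(char b) {
        base.push_back(b);
        out.push_back(std::vector<std::pair<int, double> >());
        return (int)base.size() - 1;
    }

    void add_edge(int u, int v, double w) {
        for (size_t i = 0; i < out[u].size(); ++i)
            if (out[u][i].first == v) { out[u][i].second += w; return; }
        out[u].push_back(std::make_pair(v, w));
    }

    size_t n() const { return base.size(); }

    // deterministic topological order (Kahn, smallest id first)
    std::vector<int> topo() const {
        std::vector<int> indeg(n(), 0), order;
        for (size_t u = 0; u < n(); ++u)
            for (size_t i = 0; i < out[u].size(); ++i) indeg[out[u][i].first]++;
        std::priority_queue<int, std::vector<int>, std::greater<int> > q;
        for (size_t u = 0; u < n(); ++u) if (indeg[u] == 0) q.push((int)u);
        while (!q.empty()) {
            int u = q.top(); q.pop();
            order.push_back(u);
            for (size_t i = 0; i < out[u].size(); ++i)
                if (--indeg[out[u][i].first] == 0) q.push(out[u][i].first);
        }
        return order;
    }

    void seed(const std::string &s) {
        int prev = -1;
        for (size_t i = 0; i < s.size(); ++i) {
            int v = add_node(s[i]);
            if (prev >= 0) add_edge(prev, v, 1.0);
            prev = v;
        }
    }

    // Align `s` to the graph and thread it in, incrementing edge weights.
    void add_sequence(const std::string &s) {
        if (n() == 0) { seed(s); return; }
        const int L = (int)s.size();
        if (L == 0) return;
        std::vector<int> order = topo();
        std::vector<int> pos_of(n());
        for (size_t i = 0; i < order.size(); ++i) pos_of[order[i]] = (int)i;
        // in-edges per node for the DP
        std::vector<std::vector<int> > preds(n());
        for (size_t u = 0; u < n(); ++u)
            for (size_t i = 0; i < out[u].size(); ++i)
                preds[out[u][i].first].push_back((int)u);
        const double NEG = -1e18;
        // M[v][j]: best score, v = last consumed node, j read bases consumed
        std::vector<std::vector<double> > M(n(), std::vector<double>(L + 1, NEG));
        // ops: 0 diag-from-pred, 1 delete-node, 2 insert-read-base, 3 free-start-diag
        std::vector<std::vector<signed char> > op(n(), std::vector<signed char>(L + 1, -1));
        std::vector<std::vector<int> > pred(n(), std::vector<int>(L + 1, -1));

        for (size_t oi = 0; oi < order.size(); ++oi) {
            int v = order[oi];
            for (int j = 1; j <= L; ++j) {
                int s_vj = (toupper(base[v]) == toupper(s[j - 1])) ? match : mismatch;
                // free graph start: read[0..j-1) are leading insertions
                double best = gap * (double)(j - 1) + s_vj;
                signed char bop = 3;
                int bpred = -1;
                for (size_t pi = 0; pi < preds[v].size(); ++pi) {
                    int u = preds[v][pi];
                    double c = M[u][j - 1] + s_vj;                 // diag
                    if (c > best) { best = c; bop = 0; bpred = u; }
                    c = M[u][j] + gap;                             // skip node
                    if (c > best) { best = c; bop = 1; bpred = u; }
                }
                double c = M[v][j - 1] + gap;                      // insert base
                if (c > best) { best = c; bop = 2; bpred = v; }
                M[v][j] = best; op[v][j] = bop; pred[v][j] = bpred;
            }
        }
        // best end (graph end free): max over v of M[v][L]
        int bv = -1; double bs = NEG;
        for (size_t oi = 0; oi < order.size(); ++oi) {
            int v = order[oi];
            if (M[v][L] > bs) { bs = M[v][L]; bv = v; }
        }
        if (bv < 0) { seed(s); return; }
        // traceback: list of (consumed node or -1 for new-needed, read idx)
        struct Step { int node; int j; signed char kind; }; // kind 0 diag, 2 ins
        std::vector<Step> steps;
        int v = bv, j = L;
        while (j > 0) {
            signed char o = op[v][j];
            if (o == 0 || o == 3) {
                Step st; st.node = v; st.j = j - 1; st.kind = 0;
                steps.push_back(st);
                int pv = pred[v][j];
                --j;
                if (o == 3) {
                    // leading read bases are insertions before the graph
                    while (j > 0) {
                        Step si; si.node = -1; si.j = j - 1; si.kind = 2;
                        steps.push_back(si);
                        --j;
                    }
                    break;
                }
                v = pv;
            } else if (o == 1) {
                v = pred[v][j]; // node skipped: deletion in read
            } else { // insertion
                Step st; st.node = -1; st.j = j - 1; st.kind = 2;
                steps.push_back(st);
                --j;
            }
        }
        std::reverse(steps.begin(), steps.end());
        // thread the read through the graph
        int prev = -1;
        for (size_t i = 0; i < steps.size(); ++i) {
            int node = steps[i].node;
            char rb = s[steps[i].j];
            int target;
            if (node >= 0 && toupper(base[node]) == toupper(rb)) {
                target = node;
            } else {
                target = add_node(rb); // mismatch branch or insertion node
            }
            if (prev >= 0) add_edge(prev, target, 1.0);
            prev = target;
        }
    }

    // heaviest path under `w`; deterministic tie-break on smaller pred id
    std::vector<int> heaviest_path(const std::vector<std::vector<double> > &w) const {
        std::vector<int> order = topo();
        std::vector<double> dp(n(), 0.0);
        std::vector<int> from(n(), -1);
        for (size_t oi = 0; oi < order.size(); ++oi) {
            int u = order[oi];
            for (size_t i = 0; i < out[u].size(); ++i) {
                int v = out[u][i].first;
                double c = dp[u] + w[u][i];
                if (c > dp[v] || (c == dp[v] && from[v] > u)) { dp[v] = c; from[v] = u; }
            }
        }
        int bv = -1; double bs = -1.0;
        for (size_t oi = 0; oi < order.size(); ++oi) {
            int v = order[oi];
            if (dp[v] > bs) { bs = dp[v]; bv = v; }
        }
        std::vector<int> path;
        for (int v = bv; v >= 0; v = from[v]) path.push_back(v);
        std::reverse(path.begin(), path.end());
        return path;
    }

    std::string path_string(const std::vector<int> &p) const {
        std::string s;
        for (size_t i = 0; i < p.size(); ++i) s.push_back(base[p[i]]);
        return s;
    }
};

// fitting alignment score: `read` global, `target` ends free
int fit_score_one(const std::string &read, const std::string &target,
                  int match, int mismatch, int gap) {
    const int n = (int)target.size(), m = (int)read.size();
    if (m == 0) return 0;
    std::vector<int> prev(m + 1), cur(m + 1);
    const int NEG = -1000000000;
    for (int j = 0; j <= m; ++j) prev[j] = (j == 0) ? 0 : gap * j;
    int best = prev[m];
    for (int i = 1; i <= n; ++i) {
        cur[0] = 0; // free leading target
        for (int j = 1; j <= m; ++j) {
            int s = (toupper(target[i - 1]) == toupper(read[j - 1])) ? match : mismatch;
            int v = prev[j - 1] + s;
            if (prev[j] + gap > v) v = prev[j] + gap;
            if (cur[j - 1] + gap > v) v = cur[j - 1] + gap;
            cur[j] = v;
        }
        if (cur[m] > best) best = cur[m]; // free trailing target
        std::swap(prev, cur);
    }
    return best > NEG ? best : NEG;
}

} // namespace

// [[Rcpp::export]]
List cpp_poa_consensus(CharacterVector seqs, int match = 2, int mismatch = -4,
                       int gap = -4) {
    const int n = seqs.size();
    if (n == 0) return List::create(_["cons"] = CharacterVector(0));
    Poa g(match, mismatch, gap);
    for (int i = 0; i < n; ++i) g.add_sequence(as<std::string>(seqs[i]));

    std::vector<std::vector<double> > w(g.n());
    for (size_t u = 0; u < g.n(); ++u) {
        w[u].resize(g.out[u].size());
        for (size_t i = 0; i < g.out[u].size(); ++i) w[u][i] = g.out[u][i].second;
    }
    std::vector<int> p1 = g.heaviest_path(w);
    std::string c1 = g.path_string(p1);
    // zero out the first path's edges, rerun for the alternate haplotype
    for (size_t i = 0; i + 1 < p1.size(); ++i) {
        int u = p1[i], v = p1[i + 1];
        for (size_t e = 0; e < g.out[u].size(); ++e)
            if (g.out[u][e].first == v) w[u][e] = 0.0;
    }
    std::vector<int> p2 = g.heaviest_path(w);
    std::string c2 = g.path_string(p2);
    CharacterVector cons;
    if (!c2.empty() && c2 != c1) cons = CharacterVector::create(c1, c2);
    else cons = CharacterVector::create(c1);
    return List::create(_["cons"] = cons, _["n_nodes"] = (int)g.n());
}

// Fitting-alignment scores of each read against each target sequence
// (reads global, target ends free). Used to assign read support to
// consensus haplotypes.
// [[Rcpp::export]]
IntegerMatrix cpp_fit_scores(CharacterVector reads, CharacterVector targets,
                             int match = 2, int mismatch = -4, int gap = -4) {
    IntegerMatrix out(reads.size(), targets.size());
    for (int i = 0; i < reads.size(); ++i) {
        std::string r = as<std::string>(reads[i]);
        for (int j = 0; j < targets.size(); ++j)
            out(i, j) = fit_score_one(r, as<std::string>(targets[j]), match, mismatch, gap);
    }
    return out;
}
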