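#include <Rcpp.h>
#include <string>
#include <vector>
#include <map>
#include <algorithm>
using namespace Rcpp;

// De Bruijn local assembler: nodes are k-mers, edges are (k+1)-mers with
// coverage equal to their multiplicity across the input reads. Haplotype
// contigs are extracted by depth-first search that prioritises the edge with
// the highest coverage (lexicographically smaller target k-mer on ties), so
// assembly is deterministic for a fixed read multiset. A path's score is the
// minimum edge coverage along it.

namespace {

struct Graph {
    std::vector<std::string> kmer;               // node id -> k-mer
    std::map<std::string, int> id;               // k-mer -> node id
    std::vector<std::vector<std::pair<int, int> > > out; // (to, cov)
    std::vector<int> indeg;

    int get(const std::string &s) {
        std::map<std::string, int>::iterator it = id.find(s);
        if (it != id.end()) return it->second;
        int v = (int)kmer.size();
        id[s] = v;
        kmer.push_back(s);
        out.push_back(std::vector<std::pair<int, int> >());
        indeg.push_back(0);
        return v;
    }
};

bool clean_kmer(const std::string &s) {
    for (size_t i = 0; i < s.size(); ++i) {
        char c = s[i];
        if (c != 'A' && c != 'C' && c != 'G' && c != 'T') return false;
    }
    return true;
}

// true if the graph has a directed cycle
bool is_cyclic(const Graph &g) {
    const int n = (int)g.kmer.size();
    std::vector<int> color(n, 0); // 0 white, 1 grey, 2 black
    std::vector<std::pair<int, size_t> > stack;
    for (int s = 0; s < n; ++s) {
        if (color[s] != 0) continue;
        stack.push_back(std::make_pair(s, (size_t)0));
        color[s] = 1;
        while (!stack.empty()) {
            int u = stack.back().first;
            size_t &ei = stack.back().second;
            if (ei < g.out[u].size()) {
                int v = g.out[u][ei++].first;
                if (color[v] == 1) return true;
                if (color[v] == 0) {
                    color[v] = 1;
                    stack.push_back(std::make_pair(v, (size_t)0));
                }
            } else {
                color[u] = 2;
                stack.pop_back();
            }
        }
    }
    return false;
}

struct Dfs {
    const Graph *g;
    int max_paths;
    std::vector<std::string> contigs;
    std::vector<int> scores;
    std::vector<int> path;
    std::vector<bool> on_path;

    void emit(int min_cov) {
        if ((int)contigs.size() >= max_paths) return;
        std::string s = g->kmer[path[0]];
        for (size_t i = 1; i < path.size(); ++i)
            s.push_back(g->kmer[path[i]][g->kmer[path[i]].size() - 1]);
        contigs.push_back(s);
        scores.push_back(min_cov);
    }

    void run(int u, int min_cov) {
        if ((int)contigs.size() >= max_paths) return;
        path.push_back(u);
        on_path[u] = true;
        // edges by coverage desc, then target k-mer lexicographic asc
        std::vector<std::pair<int, int> > edges = g->out[u];
        std::stable_sort(edges.begin(), edges.end(), EdgeCmp(g));
        bool extended = false;
        for (size_t i = 0; i < edges.size(); ++i) {
            int v = edges[i].first;
            if (on_path[v]) continue; // cycle guard (cyclic graphs: truncate)
            extended = true;
            run(v, std::min(min_cov, edges[i].second));
        }
        if (!extended) emit(min_cov);
        on_path[u] = false;
        path.pop_back();
    }

    struct EdgeCmp {
        const Graph *g;
        EdgeCmp(const Graph *gg) : g(gg) {}
        bool operator()(const std::pair<int, int> &a, const std::pair<int, int> &b) const {
            if (a.second != b.second) return a.second > b.second;
            return g->kmer[a.first] < g->kmer[b.first];
        }
    };
};

} // namespace

// [[Rcpp::export]]
List cpp_debruijn(CharacterVector reads, int k, int min_cov = 3, int max_paths = 32) {
    // count (k+1)-mer edges
    std::map<std::string, int> edge_cov;
    for (int r = 0; r < reads.size(); ++r) {
        std::string s = as<std::string>(reads[r]);
        for (size_t i = 0; i < s.size(); ++i) s[i] = toupper(s[i]);
        if ((int)s.size() < k + 1) continue;
        for (size_t i = 0; i + k + 1 <= s.size(); ++i) {
            std::string e = s.substr(i, k + 1);
            if (clean_kmer(e)) edge_cov[e]++;
        }
    }
    Graph g;
    int n_edges = 0;
    for (std::map<std::string, int>::iterator it = edge_cov.begin();
         it != edge_cov.end(); ++it) {
        if (it->second < min_cov) continue;
        int u = g.get(it->first.substr(0, k));
        int v = g.get(it->first.substr(1, k));
        g.out[u].push_back(std::make_pair(v, it->second));
        g.indeg[v]++;
        ++n_edges;
    }
    bool cyclic = is_cyclic(g);

    Dfs dfs;
    dfs.g = &g;
    dfs.max_paths = max_paths;
    dfs.on_path.assign(g.kmer.size(), false);
    // sources in lexicographic k-mer order (std::map iteration order)
    for (std::map<std::string, int>::iterator it = g.id.begin(); it != g.id.end(); ++it) {
        int u = it->second;
        if (g.indeg[u] == 0) dfs.run(u, 1000000000);
    }
    return List::create(_["cyclic"] = cyclic,
                        _["n_nodes"] = (int)g.kmer.size(),
                        _["n_edges"] = n_edges,
                        _["contigs"] = wrap(dfs.contigs),
                        _["scores"] = wrap(dfs.scores));
}
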