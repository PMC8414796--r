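#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Parse a CIGAR string into (op, len) pairs. Returns false on garbage.
static bool parse_cigar(const std::string &cig, std::vector<std::pair<char, int> > &out) {
    out.clear();
    if (cig.empty() || cig == "*") return false;
    size_t i = 0;
    while (i < cig.size()) {
        int len = 0;
        if (!isdigit(cig[i])) return false;
        while (i < cig.size() && isdigit(cig[i])) {
            len = len * 10 + (cig[i] - '0');
            ++i;
        }
        if (i >= cig.size() || len <= 0) return false;
        char op = cig[i++];
        switch (op) {
        case 'M': case 'I': case 'D': case 'N': case 'S': case 'H': case 'P':
        case '=': case 'X':
            out.push_back(std::make_pair(op, len));
            break;
        default:
            return false;
        }
    }
    return !out.empty();
}

static int query_len(const std::vector<std::pair<char, int> > &ops) {
    int n = 0;
    for (size_t i = 0; i < ops.size(); ++i) {
        char op = ops[i].first;
        if (op == 'M' || op == 'I' || op == 'S' || op == '=' || op == 'X')
            n += ops[i].second;
    }
    return n;
}

static int base_col(char b) {
    switch (b) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4; // N and anything else
    }
}

// Per-position pileup summary over [block_start, block_end) (0-based half-open).
// `ref` is the full chromosome sequence. `starts` are 0-based leftmost
// reference positions. Quality strings are Phred+33; "*" means absent.
// Columns of the count matrix: A C G T N I D.
// [[Rcpp::export]]
List cpp_pileup(CharacterVector seqs, CharacterVector quals, IntegerVector starts,
                CharacterVector cigars, std::string ref, int block_start, int block_end) {
    const int len = block_end - block_start;
    if (len <= 0) stop("empty block");
    IntegerMatrix counts(len, 7);
    IntegerVector S(len), depth(len);
    std::vector<int> ins_pos, del_pos;
    std::vector<std::string> ins_seq, del_seq;
    int skipped = 0, no_qual = 0;
    std::vector<std::pair<char, int> > ops;

    const int n = seqs.size();
    for (int r = 0; r < n; ++r) {
        std::string seq = as<std::string>(seqs[r]);
        std::string qual = as<std::string>(quals[r]);
        std::string cig = as<std::string>(cigars[r]);
        if (!parse_cigar(cig, ops)) { ++skipped; continue; }
        if (query_len(ops) != (int)seq.size()) { ++skipped; continue; }
        bool has_qual = (qual.size() == seq.size());
        if (!has_qual) ++no_qual;
        int rpos = starts[r]; // 0-based reference cursor
        int qpos = 0;
        // A read showing an indel contributes to the I/D count at the anchor
        // position instead of the anchor's base count: track the last aligned
        // base so it can be retracted when an indel follows.
        bool last_m = false, last_mm = false;
        int last_m_pos = -1, last_m_col = -1, last_m_q = 0;
        for (size_t oi = 0; oi < ops.size(); ++oi) {
            char op = ops[oi].first;
            int L = ops[oi].second;
            if (op == 'M' || op == '=' || op == 'X') {
                for (int j = 0; j < L; ++j, ++rpos, ++qpos) {
                    if (rpos < block_start || rpos >= block_end) {
                        if (rpos == block_start - 1 || rpos == block_end) last_m = false;
                        continue;
                    }
                    int idx = rpos - block_start;
                    char b = seq[qpos];
                    counts(idx, base_col(b))++;
                    depth[idx]++;
                    char rb = (rpos < (int)ref.size()) ? toupper(ref[rpos]) : 'N';
                    char ub = toupper(b);
                    bool mm = (ub != rb && ub != 'N' && rb != 'N');
                    if (mm && has_qual) S[idx] += (int)qual[qpos] - 33;
                    last_m = true; last_m_pos = rpos; last_m_col = base_col(b);
                    last_mm = mm; last_m_q = has_qual ? ((int)qual[qpos] - 33) : 0;
                }
            } else if (op == 'I') {
                int anchor = rpos - 1;
                if (anchor >= block_start && anchor < block_end) {
                    int idx = anchor - block_start;
                    if (last_m && last_m_pos == anchor) {
                        counts(idx, last_m_col)--;
                        if (last_mm) S[idx] -= last_m_q;
                    }
                    counts(idx, 5)++;
                    ins_pos.push_back(anchor);
                    ins_seq.push_back(seq.substr(qpos, L));
                    if (has_qual) S[idx] += (int)qual[qpos] - 33;
                }
                last_m = false;
                qpos += L;
            } else if (op == 'D' || op == 'N') {
                if (op == 'D') {
                    int anchor = rpos - 1;
                    if (anchor >= block_start && anchor < block_end) {
                        int idx = anchor - block_start;
                        if (last_m && last_m_pos == anchor) {
                            counts(idx, last_m_col)--;
                            if (last_mm) S[idx] -= last_m_q;
                        }
                        counts(idx, 6)++;
                        int e = std::min((int)ref.size(), rpos + L);
                        std::string ds = (rpos < e) ? ref.substr(rpos, e - rpos) : "";
                        for (size_t c = 0; c < ds.size(); ++c) ds[c] = toupper(ds[c]);
                        del_pos.push_back(anchor);
                        del_seq.push_back(ds);
                    }
                    // deleted positions are still spanned by the read
                    for (int j = 0; j < L; ++j) {
                        int p = rpos + j;
                        if (p >= block_start && p < block_end) depth[p - block_start]++;
                    }
                }
                last_m = false;
                rpos += L;
            } else if (op == 'S') {
                qpos += L; // soft clips contribute no evidence
            } // H, P: nothing
        }
    }

    return List::create(
        _["counts"] = counts, _["S"] = S, _["depth"] = depth,
        _["ins_pos"] = wrap(ins_pos), _["ins_seq"] = wrap(ins_seq),
        _["del_pos"] = wrap(del_pos), _["del_seq"] = wrap(del_seq),
        _["skipped"] = skipped, _["no_qual"] = no_qual);
}

// Clip reads to a reference window [reg_start, reg_end): returns the query
// bases (and qualities) laid over the window, plus the fraction of the window
// each read's aligned span covers. Inserted bases anchored strictly inside the
// window are kept; soft clips are dropped.
// [[Rcpp::export]]
List cpp_clip_reads(CharacterVector seqs, CharacterVector quals, IntegerVector starts,
                    CharacterVector cigars, int reg_start, int reg_end) {
    const int n = seqs.size();
    CharacterVector cseq(n), cqual(n);
    NumericVector overlap(n);
    LogicalVector spans(n);
    std::vector<std::pair<char, int> > ops;
    const double reg_len = reg_end - reg_start;
    for (int r = 0; r < n; ++r) {
        std::string seq = as<std::string>(seqs[r]);
        std::string qual = as<std::string>(quals[r]);
        std::string cig = as<std::string>(cigars[r]);
        std::string out, outq;
        bool has_qual = (qual.size() == seq.size());
        if (!parse_cigar(cig, ops) || query_len(ops) != (int)seq.size()) {
            cseq[r] = ""; cqual[r] = ""; overlap[r] = 0.0; spans[r] = false;
            continue;
        }
        int rpos = starts[r], qpos = 0;
        int ref_lo = starts[r], ref_hi = starts[r];
        for (size_t oi = 0; oi < ops.size(); ++oi) {
            char op = ops[oi].first;
            int L = ops[oi].second;
            if (op == 'M' || op == '=' || op == 'X') {
                for (int j = 0; j < L; ++j, ++rpos, ++qpos) {
                    if (rpos >= reg_start && rpos < reg_end) {
                        out.push_back(seq[qpos]);
                        if (has_qual) outq.push_back(qual[qpos]);
                    }
                }
                ref_hi = rpos;
            } else if (op == 'I') {
                if (rpos - 1 >= reg_start && rpos < reg_end) {
                    out.append(seq.substr(qpos, L));
                    if (has_qual) outq.append(qual.substr(qpos, L));
                }
                qpos += L;
            } else if (op == 'D' || op == 'N') {
                rpos += L;
                ref_hi = rpos;
            } else if (op == 'S') {
                qpos += L;
            }
        }
        double ov = std::min(ref_hi, reg_end) - std::max(ref_lo, reg_start);
        overlap[r] = std::max(0.0, ov) / reg_len;
        spans[r] = (ref_lo <= reg_start && ref_hi >= reg_end);
        cseq[r] = out;
        cqual[r] = has_qual ? outq : std::string("");
    }
    return List::create(_["seq"] = cseq, _["qual"] = cqual,
                        _["overlap"] = overlap, _["spans"] = spans);
}

// Reference span (M/D/N/=/X) of each CIGAR string.
// [[Rcpp::export]]
IntegerVector cpp_cigar_ref_width(CharacterVector cigars) {
    IntegerVector out(cigars.size());
    std::vector<std::pair<char, int> > ops;
    for (int i = 0; i < cigars.size(); ++i) {
        std::string cig = as<std::string>(cigars[i]);
        int w = 0;
        if (parse_cigar(cig, ops)) {
            for (size_t j = 0; j < ops.size(); ++j) {
                char op = ops[j].first;
                if (op == 'M' || op == 'D' || op == 'N' || op == '=' || op == 'X')
                    w += ops[j].second;
            }
        }
        out[i] = w;
    }
    return out;
}
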