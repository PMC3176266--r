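#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Toy nearest-neighbour folding: Nussinov-style dynamic programme whose
// score is a sum of stacking bonuses.  Pair strengths GC/CG = 3, AU/UA = 2,
// GU/UG = 1; a stack of two adjacent pairs contributes minus the sum of the
// two strengths (pseudo-kcal/mol).  Constraints: minimum hairpin loop of 3
// unpaired bases, no isolated (lonely) pairs -- every helix holds at least
// two stacked pairs.  The open chain scores 0, so the reported energy is
// always <= 0.
//
// Bases are encoded 0=A, 1=C, 2=G, 3=U.

static inline int pair_strength(int a, int b) {
    if ((a == 2 && b == 1) || (a == 1 && b == 2)) return 3; // GC
    if ((a == 0 && b == 3) || (a == 3 && b == 0)) return 2; // AU
    if ((a == 2 && b == 3) || (a == 3 && b == 2)) return 1; // GU
    return 0;
}

namespace {

constexpr double INF = std::numeric_limits<double>::infinity();

class ToyDP {
public:
    int n;
    const std::vector<int> &s;
    std::vector<double> W;   // W[i][j]: best score on [i, j]
    std::vector<double> G;   // G[i][j]: best score with (i,j), (i+1,j-1) paired
    std::vector<char> hasG;

    double w(int i, int j) const {
        if (i > j) return 0.0;
        return W[(size_t)i * n + j];
    }
    bool can_pair(int i, int j) const {
        return j - i >= 4 && pair_strength(s[i], s[j]) > 0;
    }
    double stackE(int i, int j) const {
        // stack between pairs (i,j) and (i+1,j-1)
        return -(double)(pair_strength(s[i], s[j]) +
                         pair_strength(s[i + 1], s[j - 1]));
    }

    explicit ToyDP(const std::vector<int> &seq)
        : n((int)seq.size()), s(seq),
          W((size_t)n * n, 0.0), G((size_t)n * n, INF),
          hasG((size_t)n * n, 0) {
        for (int span = 6; span < n; ++span) {
            for (int i = 0; i + span < n; ++i) {
                int j = i + span;
                size_t ij = (size_t)i * n + j;
                if (can_pair(i, j) && can_pair(i + 1, j - 1)) {
                    double inner = w(i + 2, j - 2);  // helix ends at (i+1,j-1)
                    size_t in_ij = (size_t)(i + 1) * n + (j - 1);
                    if (hasG[in_ij] && G[in_ij] < inner) inner = G[in_ij];
                    G[ij] = stackE(i, j) + inner;
                    hasG[ij] = 1;
                }
                double best = w(i, j - 1);           // j unpaired
                for (int k = i; k + 6 <= j; ++k) {   // helix (k,j)(k+1,j-1)...
                    size_t kj = (size_t)k * n + j;
                    if (!hasG[kj]) continue;
                    double v = w(i, k - 1) + G[kj];
                    if (v < best) best = v;
                }
                W[ij] = best;
            }
        }
    }

    // Traceback; ties resolved in the same order the minima were scanned:
    // j-unpaired first, then lowest helix start k, then helix termination
    // before helix extension.
    void trace_W(int i, int j, std::vector<int> &partner) const {
        while (i <= j) {
            if (j - i < 6) return;
            double wij = w(i, j);
            if (wij == w(i, j - 1)) { --j; continue; }
            for (int k = i; k + 6 <= j; ++k) {
                size_t kj = (size_t)k * n + j;
                if (!hasG[kj]) continue;
                if (w(i, k - 1) + G[kj] == wij) {
                    trace_G(k, j, partner);
                    j = k - 1;
                    break;
                }
            }
        }
    }

    void trace_G(int i, int j, std::vector<int> &partner) const {
        for (;;) {
            partner[i] = j;
            partner[j] = i;
            size_t ij = (size_t)i * n + j;
            double rest = G[ij] - stackE(i, j);
            if (rest == w(i + 2, j - 2)) {  // helix ends at (i+1,j-1)
                partner[i + 1] = j - 1;
                partner[j - 1] = i + 1;
                trace_W(i + 2, j - 2, partner);
                return;
            }
            ++i; --j;                        // helix extends
        }
    }
};

double fold_one(const std::vector<int> &seq, std::vector<int> &partner) {
    int n = (int)seq.size();
    partner.assign(n, -1);
    if (n < 7) return 0.0;
    ToyDP dp(seq);
    dp.trace_W(0, n - 1, partner);
    return dp.w(0, n - 1);
}

// base-pair distance = |symmetric difference of the two pair sets|
int bp_dist(const std::vector<int> &pa, const std::vector<int> &pb) {
    int twice = 0;
    for (size_t i = 0; i < pa.size(); ++i) {
        if (pa[i] >= 0 && pa[i] != pb[i]) ++twice;
        if (pb[i] >= 0 && pb[i] != pa[i]) ++twice;
    }
    return twice / 2;
}

} // namespace

// [[Rcpp::export]]
List c_toy_fold(IntegerVector seq) {
    std::vector<int> s = as< std::vector<int> >(seq);
    std::vector<int> partner;
    double e = fold_one(s, partner);
    return List::create(_["partner"] = wrap(partner), _["energy"] = e);
}

// Batch evaluation for the search loops: fold each sequence (given as a
// character string over ACGU), returning its energy, its base-pair
// distance to the target structure (partner-vector encoding) and its
// dot-bracket string.
// [[Rcpp::export]]
List c_toy_eval_batch(CharacterVector seqs, IntegerVector target) {
    int m = seqs.size();
    std::vector<int> tp = as< std::vector<int> >(target);
    int L = (int)tp.size();
    NumericVector dG(m);
    IntegerVector bpd(m);
    CharacterVector db(m);
    std::vector<int> s(L), partner;
    std::string buf(L, '.');
    for (int q = 0; q < m; ++q) {
        const char *str = CHAR(STRING_ELT(seqs, q));
        if ((int)LENGTH(STRING_ELT(seqs, q)) != L)
            stop("sequence length does not match the target length");
        for (int i = 0; i < L; ++i) {
            switch (str[i]) {
            case 'A': s[i] = 0; break;
            case 'C': s[i] = 1; break;
            case 'G': s[i] = 2; break;
            case 'U': s[i] = 3; break;
            default: stop("invalid residue '%c'", str[i]);
            }
        }
        dG[q] = fold_one(s, partner);
        bpd[q] = bp_dist(tp, partner);
        for (int i = 0; i < L; ++i)
            buf[i] = partner[i] < 0 ? '.' : (partner[i] > i ? '(' : ')');
        db[q] = buf;
    }
    return List::create(_["dG"] = dG, _["bpd"] = bpd, _["db"] = db);
}

// Neutrality under the toy backend: fold the wild type and all 3L
// single-point mutants, return mean over mutants of 1 - d_bp / L.
// [[Rcpp::export]]
double c_toy_neutrality(IntegerVector seq) {
    std::vector<int> s = as< std::vector<int> >(seq);
    int L = (int)s.size();
    std::vector<int> wt, mp;
    fold_one(s, wt);
    double total = 0.0;
    for (int pos = 0; pos < L; ++pos) {
        int orig = s[pos];
        for (int b = 0; b < 4; ++b) {
            if (b == orig) continue;
            s[pos] = b;
            fold_one(s, mp);
            total += 1.0 - (double)bp_dist(wt, mp) / L;
        }
        s[pos] = orig;
    }
    return total / (3.0 * L);
}
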