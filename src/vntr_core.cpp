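#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>
#include <climits>

using namespace Rcpp;

// Unit-cost Levenshtein distance, two-row DP.
static int levenshtein(const std::string& a, const std::string& b) {
    const int n = (int)a.size(), m = (int)b.size();
    if (n == 0) return m;
    if (m == 0) return n;
    std::vector<int> prev(m + 1), cur(m + 1);
    for (int j = 0; j <= m; ++j) prev[j] = j;
    for (int i = 1; i <= n; ++i) {
        cur[0] = i;
        const char ca = a[i - 1];
        for (int j = 1; j <= m; ++j) {
            int sub = prev[j - 1] + (ca != b[j - 1]);
            cur[j] = std::min(std::min(prev[j] + 1, cur[j - 1] + 1), sub);
        }
        std::swap(prev, cur);
    }
    return prev[m];
}

// [[Rcpp::export(name = ".cpp_edit_distance")]]
int cpp_edit_distance(std::string a, std::string b) {
    return levenshtein(a, b);
}

// Banded Levenshtein with an upper limit: returns the exact distance if it is
// <= limit, otherwise limit + 1. Band half-width grows with the limit only.
// [[Rcpp::export(name = ".cpp_edit_distance_bounded")]]
int cpp_edit_distance_bounded(std::string a, std::string b, int limit) {
    const int n = (int)a.size(), m = (int)b.size();
    if (limit < 0) limit = 0;
    if (std::abs(n - m) > limit) return limit + 1;
    const int INF = limit + 1;
    // dp over diagonal band of half-width `limit`
    std::vector<int> prev(2 * limit + 1, INF), cur(2 * limit + 1, INF);
    // prev[k] = D[i-1][j] where j = (i-1) + (k - limit)
    for (int k = limit; k <= std::min(2 * limit, limit + m); ++k)
        prev[k] = k - limit; // row 0: D[0][j] = j
    if (n == 0) return std::min(m, INF);
    for (int i = 1; i <= n; ++i) {
        std::fill(cur.begin(), cur.end(), INF);
        const char ca = a[i - 1];
        int klo = std::max(0, limit - i);
        int khi = std::min(2 * limit, limit + m - i);
        for (int k = klo; k <= khi; ++k) {
            const int j = i + k - limit;
            int best = INF;
            if (j == 0) {
                best = i;
            } else {
                int diag = prev[k];                       // D[i-1][j-1]
                if (diag < INF) best = std::min(best, diag + (ca != b[j - 1]));
                if (k + 1 <= 2 * limit && prev[k + 1] < INF)
                    best = std::min(best, prev[k + 1] + 1);  // D[i-1][j] + 1
                if (k - 1 >= 0 && cur[k - 1] < INF)
                    best = std::min(best, cur[k - 1] + 1);   // D[i][j-1] + 1
            }
            cur[k] = std::min(best, INF);
        }
        std::swap(prev, cur);
    }
    int k = limit + m - n;
    if (k < 0 || k > 2 * limit) return INF;
    return std::min(prev[k], INF);
}

// Fitting alignment: query aligned globally, reference end-gaps free.
// Returns the minimum edit distance of query against any substring of ref.
// [[Rcpp::export(name = ".cpp_fit_align_cost")]]
int cpp_fit_align_cost(std::string query, std::string ref) {
    const int n = (int)query.size(), m = (int)ref.size();
    if (n == 0) return 0;
    std::vector<int> prev(m + 1), cur(m + 1);
    for (int j = 0; j <= m; ++j) prev[j] = 0;     // free start in ref
    for (int i = 1; i <= n; ++i) {
        cur[0] = i;
        const char ca = query[i - 1];
        for (int j = 1; j <= m; ++j) {
            int sub = prev[j - 1] + (ca != ref[j - 1]);
            cur[j] = std::min(std::min(prev[j] + 1, cur[j - 1] + 1), sub);
        }
        std::swap(prev, cur);
    }
    return *std::min_element(prev.begin(), prev.end()); // free end in ref
}

// ---------------------------------------------------------------------------
// Sequence decomposition into a tiling of motif-assigned blocks minimizing
// total edit distance. DP over suffixes so reconstruction from the left gives
// leftmost-longest tie-breaking. Ties: cost, then fewest blocks, then longest
// (leftmost) block, then lowest motif index.
// Returns list(start, end, motif, cost) (0-based half-open) + total.
// [[Rcpp::export(name = ".cpp_decompose")]]
List cpp_decompose(std::string seq, std::vector<std::string> motifs,
                   int max_block) {
    const int n = (int)seq.size();
    const int K = (int)motifs.size();
    if (K == 0) stop("motif list is empty");
    if (max_block < 1) max_block = n;
    const long INF = LONG_MAX / 4;
    std::vector<long> cost(n + 1, INF);
    std::vector<int> nblk(n + 1, INT_MAX / 4);
    std::vector<int> chooseL(n + 1, -1), chooseM(n + 1, -1);
    cost[n] = 0; nblk[n] = 0;
    std::vector<int> row, nrow;
    for (int i = n - 1; i >= 0; --i) {
        long bCost = INF; int bBlk = INT_MAX / 4, bL = -1, bM = -1;
        const int W = std::min(max_block, n - i);
        for (int mi = 0; mi < K; ++mi) {
            const std::string& mo = motifs[mi];
            const int ml = (int)mo.size();
            row.assign(ml + 1, 0);
            for (int j = 0; j <= ml; ++j) row[j] = j;
            for (int L = 1; L <= W; ++L) {
                nrow.assign(ml + 1, 0);
                nrow[0] = L;
                const char c = seq[i + L - 1];
                for (int j = 1; j <= ml; ++j) {
                    int sub = row[j - 1] + (c != mo[j - 1]);
                    nrow[j] = std::min(std::min(row[j] + 1, nrow[j - 1] + 1), sub);
                }
                row.swap(nrow);
                const long cand = (long)row[ml] + cost[i + L];
                const int candB = nblk[i + L] + 1;
                bool better = false;
                if (cand < bCost) better = true;
                else if (cand == bCost) {
                    if (candB < bBlk) better = true;
                    else if (candB == bBlk) {
                        if (L > bL) better = true;
                        else if (L == bL && mi < bM) better = true;
                    }
                }
                if (better) { bCost = cand; bBlk = candB; bL = L; bM = mi; }
            }
        }
        cost[i] = bCost; nblk[i] = bBlk; chooseL[i] = bL; chooseM[i] = bM;
    }
    // reconstruct from the left
    std::vector<int> starts, ends, midx, bcost;
    int pos = 0;
    while (pos < n) {
        const int L = chooseL[pos], mi = chooseM[pos];
        starts.push_back(pos);
        ends.push_back(pos + L);
        midx.push_back(mi + 1); // 1-based for R
        bcost.push_back(levenshtein(seq.substr(pos, L), motifs[mi]));
        pos += L;
    }
    return List::create(_["start"] = starts, _["end"] = ends,
                        _["motif"] = midx, _["cost"] = bcost,
                        _["total"] = (double)cost[0]);
}

// ---------------------------------------------------------------------------
// Exact branch-and-bound for efficient motif selection.
// minimize lambda * |T| + sum_i o_i * min_{j in T, o_j >= o_i} d_ij
// s.t. total replacement cost <= budget (integer), T nonempty, every motif
// has a representative in T with count >= its own.
// Ties among optima: lexicographically smallest sorted selected-motif list.
//
// Representative assignment per motif given T: valid j minimizing d_ij,
// ties by larger o_j, then lexicographically smaller motif.
namespace {

struct BnB {
    int p;
    std::vector<int> o;
    std::vector<std::vector<int>> d;
    std::vector<std::string> motifs;
    long budget;
    double lambda;
    // state: 0 undecided, 1 in, 2 out
    std::vector<int> state;
    std::vector<int> order;
    double bestObj;
    bool haveBest;
    std::vector<int> bestSet;      // sorted original indices
    std::vector<int> bestAssign;
    long bestCost;
    long nodes, nodeCap;
    bool capped;

    static bool lexLess(const std::vector<std::string>& a,
                        const std::vector<std::string>& b) {
        return std::lexicographical_compare(a.begin(), a.end(),
                                            b.begin(), b.end());
    }

    std::vector<std::string> motifList(const std::vector<int>& idx) const {
        std::vector<std::string> v;
        v.reserve(idx.size());
        for (int i : idx) v.push_back(motifs[i]);
        std::sort(v.begin(), v.end());
        return v;
    }

    // assignment of i among candidate set mask (state != 2 for bound, or
    // state == 1 for leaf); returns -1 if none valid
    int bestRep(int i, bool leaf) const {
        int bj = -1;
        for (int j = 0; j < p; ++j) {
            const int st = state[j];
            if (leaf ? (st != 1) : (st == 2)) continue;
            if (o[j] < o[i]) continue;
            if (bj < 0) { bj = j; continue; }
            if (d[i][j] < d[i][bj]) { bj = j; continue; }
            if (d[i][j] == d[i][bj]) {
                if (o[j] > o[bj] || (o[j] == o[bj] && motifs[j] < motifs[bj]))
                    bj = j;
            }
        }
        return bj;
    }

    void leaf() {
        std::vector<int> T;
        for (int j = 0; j < p; ++j) if (state[j] == 1) T.push_back(j);
        if (T.empty()) return;
        std::vector<int> assign(p, -1);
        long cst = 0;
        for (int i = 0; i < p; ++i) {
            int j = bestRep(i, true);
            if (j < 0) return; // infeasible
            assign[i] = j;
            cst += (long)o[i] * d[i][j];
            if (cst > budget) return;
        }
        const double obj = lambda * (double)T.size() + (double)cst;
        if (!haveBest || obj < bestObj - 1e-9) {
            haveBest = true; bestObj = obj; bestSet = T;
            bestAssign = assign; bestCost = cst;
        } else if (std::abs(obj - bestObj) <= 1e-9) {
            if (lexLess(motifList(T), motifList(bestSet))) {
                bestSet = T; bestAssign = assign; bestCost = cst;
            }
        }
    }

    void dfs(int k) {
        if (capped) return;
        if (++nodes > nodeCap) { capped = true; return; }
        // bounds
        long lb = 0;
        int nin = 0;
        for (int j = 0; j < p; ++j) if (state[j] == 1) ++nin;
        for (int i = 0; i < p; ++i) {
            int j = bestRep(i, false);
            if (j < 0) return; // no possible representative
            lb += (long)o[i] * d[i][j];
            if (lb > budget) return;
        }
        const double lbObj = lambda * (double)std::max(nin, 1) + (double)lb;
        if (haveBest && lbObj > bestObj + 1e-9) return;
        if (k == p) { leaf(); return; }
        const int j = order[k];
        state[j] = 1; dfs(k + 1);
        state[j] = 2; dfs(k + 1);
        state[j] = 0;
    }
};

} // namespace

// [[Rcpp::export(name = ".cpp_select_bnb")]]
List cpp_select_bnb(IntegerVector counts, IntegerMatrix dist,
                    std::vector<std::string> motifs, double budget,
                    double lambda, double node_cap) {
    BnB s;
    s.p = counts.size();
    s.o.assign(counts.begin(), counts.end());
    s.d.assign(s.p, std::vector<int>(s.p));
    for (int i = 0; i < s.p; ++i)
        for (int j = 0; j < s.p; ++j) s.d[i][j] = dist(i, j);
    s.motifs = motifs;
    s.budget = (long)budget;
    s.lambda = lambda;
    s.state.assign(s.p, 0);
    s.order.resize(s.p);
    for (int i = 0; i < s.p; ++i) s.order[i] = i;
    // process high-count motifs first (they are likely representatives)
    std::sort(s.order.begin(), s.order.end(), [&](int a, int b) {
        if (s.o[a] != s.o[b]) return s.o[a] > s.o[b];
        return s.motifs[a] < s.motifs[b];
    });
    s.haveBest = false; s.bestObj = 0; s.bestCost = 0;
    s.nodes = 0; s.nodeCap = (long)node_cap; s.capped = false;
    s.dfs(0);
    if (s.capped) stop("branch-and-bound node cap exceeded");
    if (!s.haveBest) stop("no feasible selection (budget too small)");
    IntegerVector sel(s.bestSet.begin(), s.bestSet.end());
    IntegerVector asg(s.bestAssign.begin(), s.bestAssign.end());
    return List::create(_["selected"] = sel + 1, _["assignment"] = asg + 1,
                        _["cost"] = (double)s.bestCost,
                        _["objective"] = s.bestObj);
}
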