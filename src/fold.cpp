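#include <Rcpp.h>
#include <vector>
#include <string>
#include <array>
using namespace Rcpp;

// Pair scores on the internal DNA alphabet (T stands for U):
// G:C = 3, A:T = 2, G:T wobble = 1, everything else unpairable.
static inline int pair_score(char a, char b) {
    if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return 3;
    if ((a == 'A' && b == 'T') || (a == 'T' && b == 'A')) return 2;
    if ((a == 'G' && b == 'T') || (a == 'T' && b == 'G')) return 1;
    return 0;
}

static const int MIN_LOOP = 3;   // unpaired bases enclosed by a pair
static const int STACK = 2;      // bonus when a pair stacks on another
static const int NEG = -1000000;

// Maximum-score nested structure under a stacking-aware scheme: each
// pair contributes its pair score, plus STACK when it is directly
// enclosed by the adjacent pair (i+1,j-1 inside i,j), mirroring the
// dominance of helix stacking in nearest-neighbor energy models.
// Two-state DP: B[i][j] = best score for region [i,j];
// P[i][j] = best score for [i,j] given (i,j) paired.
// Deterministic traceback: prefer leaving j unpaired, then the
// smallest pairing partner k; inside a helix prefer the stacked
// continuation.
// [[Rcpp::export(name = ".nussinov_fold")]]
List nussinov_fold(std::string seq) {
    int n = seq.size();
    std::vector<std::vector<int>> B(n, std::vector<int>(n, 0));
    std::vector<std::vector<int>> P(n, std::vector<int>(n, NEG));
    for (int span = MIN_LOOP + 1; span < n; ++span) {
        for (int i = 0; i + span < n; ++i) {
            int j = i + span;
            int ps = pair_score(seq[i], seq[j]);
            if (ps > 0) {
                int inner = B[i + 1][j - 1];
                int stacked = (P[i + 1][j - 1] > NEG)
                                  ? P[i + 1][j - 1] + STACK : NEG;
                P[i][j] = ps + std::max(inner, stacked);
            }
            int best = B[i][j - 1];
            for (int k = i; k <= j - MIN_LOOP - 1; ++k) {
                if (P[k][j] == NEG) continue;
                int left = (k > i) ? B[i][k - 1] : 0;
                int cand = left + P[k][j];
                if (cand > best) best = cand;
            }
            B[i][j] = best;
        }
    }

    std::string db(n, '.');
    // stack entries: (i, j, state) with state 0 = B, 1 = P
    std::vector<std::array<int, 3>> st;
    if (n > 0) st.push_back({0, n - 1, 0});
    while (!st.empty()) {
        int i = st.back()[0], j = st.back()[1], state = st.back()[2];
        st.pop_back();
        if (j - i <= MIN_LOOP && state == 0) continue;
        if (state == 0) {
            if (B[i][j] == B[i][j - 1]) {
                st.push_back({i, j - 1, 0});
                continue;
            }
            for (int k = i; k <= j - MIN_LOOP - 1; ++k) {
                if (P[k][j] == NEG) continue;
                int left = (k > i) ? B[i][k - 1] : 0;
                if (left + P[k][j] == B[i][j]) {
                    st.push_back({k, j, 1});
                    if (k > i) st.push_back({i, k - 1, 0});
                    break;
                }
            }
        } else {
            db[i] = '(';
            db[j] = ')';
            int ps = pair_score(seq[i], seq[j]);
            if (P[i + 1][j - 1] > NEG &&
                P[i][j] == ps + P[i + 1][j - 1] + STACK) {
                st.push_back({i + 1, j - 1, 1});
            } else if (j - 1 - (i + 1) > MIN_LOOP) {
                st.push_back({i + 1, j - 1, 0});
            }
        }
    }

    int score = (n > 0) ? B[0][n - 1] : 0;
    return List::create(_["structure"] = db, _["score"] = score);
}
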