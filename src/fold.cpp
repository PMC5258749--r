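#include <Rcpp.h>
#include <climits>
using namespace Rcpp;

// Zuker-style minimum-free-energy folding over a simplified nearest-neighbour
// model: stacking energies for ordered pair stacks, linear hairpin / internal
// / multibranch loop penalties, minimum hairpin loop of `min_hairpin`
// unpaired bases, canonical pairs plus G.U wobble, N never pairs. Energies
// are integers in 1/100 kcal/mol so that optima compare exactly.
//
// Recurrences (0-based, i < j):
//   V(i,j)  : min energy given i pairs j
//             hairpin | interior/stack to (p,q) | multibranch closing
//   WM(i,j) : min energy of a multiloop segment holding >= 1 branch
//   W(j)    : exterior prefix minimum (unpaired exterior bases are free)
//
// Ties are resolved by a fixed deterministic backtracking order documented
// in the R wrapper.

static const int INF = INT_MAX / 4;

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1; case 'G': return 2; case 'U': return 3;
    default:  return -1; // N or anything else: never pairs
  }
}

// pair codes: AU=0, CG=1, GC=2, UA=3, GU=4, UG=5, -1 = not a pair
static inline int pair_code(int a, int b) {
  if (a == 0 && b == 3) return 0;
  if (a == 1 && b == 2) return 1;
  if (a == 2 && b == 1) return 2;
  if (a == 3 && b == 0) return 3;
  if (a == 2 && b == 3) return 4;
  if (a == 3 && b == 2) return 5;
  return -1;
}

struct FoldParams {
  IntegerMatrix stack;   // 6x6, [outer pair][inner pair]
  int hairpin_base, hairpin_slope;
  int internal_base, internal_slope;
  int ml_close, ml_branch, ml_unpaired;
  int max_loop, min_hairpin;
};

static inline int hairpin_E(const FoldParams& P, int size) {
  return P.hairpin_base + P.hairpin_slope * (size - P.min_hairpin);
}

// [[Rcpp::export]]
List fold_engine_cpp(const std::string& seq, IntegerMatrix stack,
                     int hairpin_base, int hairpin_slope,
                     int internal_base, int internal_slope,
                     int ml_close, int ml_branch, int ml_unpaired,
                     int max_loop, int min_hairpin) {
  FoldParams P{stack, hairpin_base, hairpin_slope, internal_base, internal_slope,
               ml_close, ml_branch, ml_unpaired, max_loop, min_hairpin};
  const int n = (int)seq.size();
  std::vector<int> code(n);
  for (int i = 0; i < n; ++i) code[i] = base_code(seq[i]);

  std::vector<int> pc((size_t)n * n, -1);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      pc[(size_t)i * n + j] = (code[i] < 0 || code[j] < 0) ? -1 : pair_code(code[i], code[j]);

  std::vector<int> V((size_t)n * n, INF), WM((size_t)n * n, INF);
  #define IDX(i, j) ((size_t)(i) * n + (j))

  for (int i = n - 2; i >= 0; --i) {
    for (int j = i + 1; j < n; ++j) {
      // --- V(i,j)
      int best = INF;
      if (pc[IDX(i, j)] >= 0 && j - i - 1 >= min_hairpin) {
        best = hairpin_E(P, j - i - 1);
        // interior loops / stacks (total unpaired <= max_loop)
        int pmax = std::min(j - 2, i + 1 + max_loop);
        for (int p = i + 1; p <= pmax; ++p) {
          int up_left = p - i - 1;
          int qmin = std::max(p + min_hairpin + 1, j - 1 - (max_loop - up_left));
          for (int q = qmin; q <= j - 1; ++q) {
            if (V[IDX(p, q)] >= INF) continue;
            int up = up_left + (j - q - 1);
            int e;
            if (up == 0)
              e = V[IDX(p, q)] + stack(pc[IDX(i, j)], pc[IDX(p, q)]);
            else
              e = V[IDX(p, q)] + internal_base + internal_slope * up;
            if (e < best) best = e;
          }
        }
        // multibranch: close with >= 2 branches inside
        for (int k = i + 2; k <= j - 2; ++k) {
          if (WM[IDX(i + 1, k - 1)] >= INF || WM[IDX(k, j - 1)] >= INF) continue;
          int e = ml_close + WM[IDX(i + 1, k - 1)] + WM[IDX(k, j - 1)];
          if (e < best) best = e;
        }
      }
      V[IDX(i, j)] = best;

      // --- WM(i,j)
      int wm = INF;
      if (V[IDX(i, j)] < INF) wm = V[IDX(i, j)] + ml_branch;
      if (i + 1 <= j && WM[IDX(i + 1, j)] < INF)
        wm = std::min(wm, WM[IDX(i + 1, j)] + ml_unpaired);
      if (j - 1 >= i && WM[IDX(i, j - 1)] < INF)
        wm = std::min(wm, WM[IDX(i, j - 1)] + ml_unpaired);
      for (int k = i + 1; k <= j; ++k) {
        if (WM[IDX(i, k - 1)] >= INF || WM[IDX(k, j)] >= INF) continue;
        wm = std::min(wm, WM[IDX(i, k - 1)] + WM[IDX(k, j)]);
      }
      WM[IDX(i, j)] = wm;
    }
  }

  // exterior
  std::vector<int> W(n + 1, 0);
  for (int j = 1; j <= n; ++j) {
    int w = W[j - 1];
    for (int i = 1; i < j; ++i) {
      if (V[IDX(i - 1, j - 1)] >= INF) continue;
      int e = W[i - 1] + V[IDX(i - 1, j - 1)];
      if (e < w) w = e;
    }
    W[j] = w;
  }

  // ---- deterministic traceback
  std::vector<int> pairv(n, 0); // 1-based partner, 0 = unpaired
  struct Frame { int type, i, j; }; // 0=V, 1=WM
  std::vector<Frame> st;

  int j = n;
  while (j > 0) {
    if (W[j] == W[j - 1]) { --j; continue; }
    bool found = false;
    for (int i = 1; i < j && !found; ++i) {
      if (V[IDX(i - 1, j - 1)] < INF && W[i - 1] + V[IDX(i - 1, j - 1)] == W[j]) {
        st.push_back(Frame{0, i - 1, j - 1});
        j = i - 1;
        found = true;
      }
    }
    if (!found) --j; // defensive; cannot happen
  }

  while (!st.empty()) {
    Frame f = st.back(); st.pop_back();
    int i = f.i; j = f.j;
    if (f.type == 0) {
      pairv[i] = j + 1; pairv[j] = i + 1;
      int e = V[IDX(i, j)];
      if (j - i - 1 >= P.min_hairpin && e == hairpin_E(P, j - i - 1)) continue;
      bool done = false;
      int pmax = std::min(j - 2, i + 1 + P.max_loop);
      for (int p = i + 1; p <= pmax && !done; ++p) {
        int up_left = p - i - 1;
        int qmin = std::max(p + P.min_hairpin + 1, j - 1 - (P.max_loop - up_left));
        for (int q = qmin; q <= j - 1 && !done; ++q) {
          if (V[IDX(p, q)] >= INF) continue;
          int up = up_left + (j - q - 1);
          int cand = (up == 0)
            ? V[IDX(p, q)] + P.stack(pc[IDX(i, j)], pc[IDX(p, q)])
            : V[IDX(p, q)] + P.internal_base + P.internal_slope * up;
          if (cand == e) { st.push_back(Frame{0, p, q}); done = true; }
        }
      }
      if (done) continue;
      for (int k = i + 2; k <= j - 2; ++k) {
        if (WM[IDX(i + 1, k - 1)] >= INF || WM[IDX(k, j - 1)] >= INF) continue;
        if (P.ml_close + WM[IDX(i + 1, k - 1)] + WM[IDX(k, j - 1)] == e) {
          st.push_back(Frame{1, i + 1, k - 1});
          st.push_back(Frame{1, k, j - 1});
          break;
        }
      }
    } else { // WM
      int e = WM[IDX(i, j)];
      if (i + 1 <= j && WM[IDX(i + 1, j)] < INF && e == WM[IDX(i + 1, j)] + P.ml_unpaired) {
        st.push_back(Frame{1, i + 1, j}); continue;
      }
      if (V[IDX(i, j)] < INF && e == V[IDX(i, j)] + P.ml_branch) {
        st.push_back(Frame{0, i, j}); continue;
      }
      if (j - 1 >= i && WM[IDX(i, j - 1)] < INF && e == WM[IDX(i, j - 1)] + P.ml_unpaired) {
        st.push_back(Frame{1, i, j - 1}); continue;
      }
      for (int k = i + 1; k <= j; ++k) {
        if (WM[IDX(i, k - 1)] >= INF || WM[IDX(k, j)] >= INF) continue;
        if (e == WM[IDX(i, k - 1)] + WM[IDX(k, j)]) {
          st.push_back(Frame{1, i, k - 1});
          st.push_back(Frame{1, k, j});
          break;
        }
      }
    }
  }
  #undef IDX

  return List::create(_["pair"] = wrap(pairv), _["energy"] = W[n]);
}
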