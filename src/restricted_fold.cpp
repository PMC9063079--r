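#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <utility>
#include <algorithm>

using namespace Rcpp;

// Restricted pseudoknot-free minimum free energy folding.
//
// Zuker-style W/V/M dynamic program over a sequence with hard constraints:
// 'forbidden' positions may never pair, and 'forced' positions must pair
// with their designated partner (guide pairs). O(n^3) time, O(n^2) space.
// Internal loops are capped at 30 unpaired bases total (standard).

static const double BIG = 1e9;
static const int MAXLOOP = 30;

struct FoldCtx {
  int n;
  std::vector<int> code;        // 1..4 = A C G U, 1-based
  std::vector<int> fp;          // forced partner, 0 = free
  std::vector<char> xpos;       // forbidden to pair
  std::vector<int> mpcum;       // prefix sums of must-pair flags
  // energy tables
  double stack[7][7];
  std::vector<double> hairpin, bulge, internal_;
  double extrap, ninio_slope, ninio_max, ml_a, ml_b, ml_c;
  std::vector<double> V, M, W;  // V, M: (n+2)^2; W: n+1
  int idx(int i, int j) const { return i * (n + 2) + j; }

  int ptype(int i, int j) const {
    int a = code[i], b = code[j];
    if (a == 1 && b == 4) return 1;  // AU
    if (a == 4 && b == 1) return 2;  // UA
    if (a == 2 && b == 3) return 3;  // CG
    if (a == 3 && b == 2) return 4;  // GC
    if (a == 3 && b == 4) return 5;  // GU
    if (a == 4 && b == 3) return 6;  // UG
    return 0;
  }

  bool valid_pair(int i, int j) const {
    if (j - i < 4) return false;
    if (xpos[i] || xpos[j]) return false;
    if (ptype(i, j) == 0) return false;
    if (fp[i] != 0 && fp[i] != j) return false;
    if (fp[j] != 0 && fp[j] != i) return false;
    return true;
  }

  // any must-pair position in [a, b]?
  bool any_forced(int a, int b) const {
    if (a > b) return false;
    return (mpcum[b] - mpcum[a - 1]) > 0;
  }

  double loop_tab(const std::vector<double>& tab, int size) const {
    if (size < 1) return BIG;
    if (size <= 30) return tab[size - 1] >= BIG ? BIG : tab[size - 1];
    return tab[29] + extrap * std::log((double)size / 30.0);
  }

  double interior_cost(int i, int j, int k, int l) const {
    int l1 = k - i - 1, l2 = j - l - 1;
    if (l1 == 0 && l2 == 0) return stack[ptype(i, j)][ptype(k, l)];
    if (l1 == 0 || l2 == 0) return loop_tab(bulge, l1 + l2);
    double asym = ninio_slope * std::abs(l1 - l2);
    if (asym > ninio_max) asym = ninio_max;
    return loop_tab(internal_, l1 + l2) + asym;
  }

  // same, with the outer pair type precomputed (hot interior scan)
  double interior_cost_pt(int pt_outer, int k, int l, int l1, int l2) const {
    if (l1 == 0 && l2 == 0) return stack[pt_outer][ptype(k, l)];
    if (l1 == 0 || l2 == 0) return loop_tab(bulge, l1 + l2);
    double asym = ninio_slope * std::abs(l1 - l2);
    if (asym > ninio_max) asym = ninio_max;
    return loop_tab(internal_, l1 + l2) + asym;
  }

  double hairpin_e(int i, int j) const {
    if (any_forced(i + 1, j - 1)) return BIG;
    return loop_tab(hairpin, j - i - 1);
  }
};

// Joint computation by increasing span so V's multiloop case sees M.
static void fill_joint(FoldCtx& C) {
  int n = C.n;
  C.V.assign((n + 2) * (n + 2), BIG);
  C.M.assign((n + 2) * (n + 2), BIG);
  // hoisted lookups for the bounded interior-loop scan:
  // partners[k] = sorted valid partners l > k of position k;
  // first_forced[t] = smallest must-pair position >= t (n + 1 if none);
  // last_forced[t] = largest must-pair position <= t (0 if none).
  // next_partner[k * (n + 2) + l] = smallest valid partner l' >= l of k
  // (n + 1 when none), so the interior scan can jump between candidates.
  std::vector<int> next_partner((n + 1) * (n + 2), n + 1);
  for (int k = 1; k <= n; ++k) {
    int* row = &next_partner[k * (n + 2)];
    for (int l = n; l >= 1; --l) {
      row[l] = (l >= k + 4 && C.valid_pair(k, l)) ? l : (l < n ? row[l + 1] : n + 1);
    }
  }
  std::vector<int> first_forced(n + 2, n + 1), last_forced(n + 1, 0);
  for (int t = n; t >= 1; --t) {
    first_forced[t] = (C.fp[t] != 0) ? t : first_forced[t + 1];
  }
  for (int t = 1; t <= n; ++t) {
    last_forced[t] = (C.fp[t] != 0) ? t : (t > 1 ? last_forced[t - 1] : 0);
  }
  for (int d = 0; d <= n - 1; ++d) {
    for (int i = 1; i + d <= n; ++i) {
      int j = i + d;
      // ---- V(i, j): needs V and M of shorter spans
      if (d >= 4 && C.valid_pair(i, j)) {
        double v = C.hairpin_e(i, j);
        int pt_outer = C.ptype(i, j);
        int kmax = j - 5;
        if (kmax > i + 1 + MAXLOOP) kmax = i + 1 + MAXLOOP;
        if (kmax > first_forced[i + 1]) kmax = first_forced[i + 1];
        int lfloor = last_forced[j - 1];
        for (int k = i + 1; k <= kmax; ++k) {
          int l1 = k - i - 1;
          int lmin = k + 4;
          int lo = j - 1 - (MAXLOOP - l1);
          if (lo > lmin) lmin = lo;
          if (lfloor > lmin) lmin = lfloor;
          if (lmin > j - 1) continue;
          const int* np = &next_partner[k * (n + 2)];
          const double* Vrow = &C.V[k * (n + 2)];
          for (int l = np[lmin]; l <= j - 1; l = np[l + 1]) {
            double vin = Vrow[l];
            if (vin >= BIG) continue;
            double e = C.interior_cost_pt(pt_outer, k, l, l1, j - l - 1) + vin;
            if (e < v) v = e;
          }
        }
        for (int h = i + 1; h <= j - 2; ++h) {
          double left = C.M[C.idx(i + 1, h)];
          if (left >= BIG) continue;
          double right = C.M[C.idx(h + 1, j - 1)];
          if (right >= BIG) continue;
          double e = C.ml_a + C.ml_b + left + right;
          if (e < v) v = e;
        }
        if (v < BIG) C.V[C.idx(i, j)] = v;
      }
      // ---- M(i, j): needs M(i, j-1) (same row, shorter) and V(k, j)
      double m = BIG;
      if (j > i && C.fp[j] == 0) {
        double e = C.M[C.idx(i, j - 1)];
        if (e < BIG) {
          e += C.ml_c;
          if (e < m) m = e;
        }
      }
      for (int k = i; k <= j - 4; ++k) {
        double v = C.V[C.idx(k, j)];
        if (v >= BIG) continue;
        double leftpart;
        if (k == i) leftpart = 0.0;
        else {
          leftpart = C.M[C.idx(i, k - 1)];
          if (!C.any_forced(i, k - 1)) {
            double cc = C.ml_c * (k - i);
            if (cc < leftpart) leftpart = cc;
          }
        }
        if (leftpart >= BIG) continue;
        double e = leftpart + v + C.ml_b;
        if (e < m) m = e;
      }
      if (m < BIG) C.M[C.idx(i, j)] = m;
    }
  }
  // exterior
  C.W.assign(n + 1, 0.0);
  for (int j = 1; j <= n; ++j) {
    double w = BIG;
    if (C.fp[j] == 0) w = C.W[j - 1];
    for (int k = 1; k <= j - 4; ++k) {
      double v = C.V[C.idx(k, j)];
      if (v >= BIG) continue;
      double e = C.W[k - 1] + v;
      if (e < w) w = e;
    }
    C.W[j] = w;
    if (C.W[j] > BIG) C.W[j] = BIG;
  }
}

static const double EPS = 1e-7;

struct TraceItem { int i, j, what; };  // what: 0 = W-span [1..j], 1 = V, 2 = M

static void traceback(FoldCtx& C, std::vector<std::pair<int,int> >& out) {
  int n = C.n;
  std::vector<TraceItem> stack;
  // exterior: walk W from n down
  {
    int j = n;
    while (j >= 1) {
      if (C.fp[j] == 0 && std::fabs(C.W[j] - C.W[j - 1]) < EPS) { --j; continue; }
      bool found = false;
      for (int k = 1; k <= j - 4; ++k) {
        double v = C.V[C.idx(k, j)];
        if (v >= BIG) continue;
        if (std::fabs(C.W[j] - (C.W[k - 1] + v)) < EPS) {
          TraceItem t; t.i = k; t.j = j; t.what = 1;
          stack.push_back(t);
          j = k - 1;
          found = true;
          break;
        }
      }
      if (!found) {
        if (C.fp[j] == 0) { --j; continue; }  // numeric fallback
        stop("traceback failure in exterior loop");
      }
    }
  }
  while (!stack.empty()) {
    TraceItem t = stack.back();
    stack.pop_back();
    int i = t.i, j = t.j;
    if (t.what == 1) {
      out.push_back(std::make_pair(i, j));
      double v = C.V[C.idx(i, j)];
      if (std::fabs(v - C.hairpin_e(i, j)) < EPS) continue;
      bool found = false;
      for (int l1 = 0; l1 <= MAXLOOP && !found; ++l1) {
        int k = i + 1 + l1;
        if (k > j - 5) break;
        if (C.any_forced(i + 1, k - 1)) break;
        for (int l2 = 0; l2 + l1 <= MAXLOOP; ++l2) {
          int l = j - 1 - l2;
          if (l - k < 4) break;
          if (C.any_forced(l + 1, j - 1)) continue;
          double vin = C.V[C.idx(k, l)];
          if (vin >= BIG) continue;
          if (std::fabs(v - (C.interior_cost(i, j, k, l) + vin)) < EPS) {
            TraceItem s; s.i = k; s.j = l; s.what = 1;
            stack.push_back(s);
            found = true;
            break;
          }
        }
      }
      if (found) continue;
      for (int h = i + 1; h <= j - 2 && !found; ++h) {
        double left = C.M[C.idx(i + 1, h)];
        double right = C.M[C.idx(h + 1, j - 1)];
        if (left >= BIG || right >= BIG) continue;
        if (std::fabs(v - (C.ml_a + C.ml_b + left + right)) < EPS) {
          TraceItem s1; s1.i = i + 1; s1.j = h; s1.what = 2;
          TraceItem s2; s2.i = h + 1; s2.j = j - 1; s2.what = 2;
          stack.push_back(s1);
          stack.push_back(s2);
          found = true;
        }
      }
      if (!found) stop("traceback failure in V at (%d, %d)", i, j);
    } else if (t.what == 2) {
      double m = C.M[C.idx(i, j)];
      if (j > i && C.fp[j] == 0 &&
          std::fabs(m - (C.M[C.idx(i, j - 1)] + C.ml_c)) < EPS) {
        TraceItem s; s.i = i; s.j = j - 1; s.what = 2;
        stack.push_back(s);
        continue;
      }
      bool found = false;
      for (int k = i; k <= j - 4; ++k) {
        double v = C.V[C.idx(k, j)];
        if (v >= BIG) continue;
        if (k == i) {
          if (std::fabs(m - (v + C.ml_b)) < EPS) {
            TraceItem s; s.i = i; s.j = j; s.what = 1;
            stack.push_back(s);
            found = true;
            break;
          }
        } else {
          if (!C.any_forced(i, k - 1) &&
              std::fabs(m - (C.ml_c * (k - i) + v + C.ml_b)) < EPS) {
            TraceItem s; s.i = k; s.j = j; s.what = 1;
            stack.push_back(s);
            found = true;
            break;
          }
          double mm = C.M[C.idx(i, k - 1)];
          if (mm < BIG && std::fabs(m - (mm + v + C.ml_b)) < EPS) {
            TraceItem s1; s1.i = i; s1.j = k - 1; s1.what = 2;
            TraceItem s2; s2.i = k; s2.j = j; s2.what = 1;
            stack.push_back(s1);
            stack.push_back(s2);
            found = true;
            break;
          }
        }
      }
      if (!found) stop("traceback failure in M at (%d, %d)", i, j);
    }
  }
}

// [[Rcpp::export]]
List fold_restricted_cpp(IntegerVector codes, IntegerVector forced_partner,
                         LogicalVector forbidden, NumericMatrix stack_tab,
                         NumericVector hairpin_tab, NumericVector bulge_tab,
                         NumericVector internal_tab, double extrapolation,
                         NumericVector ninio, NumericVector multi) {
  int n = codes.size();
  FoldCtx C;
  C.n = n;
  C.code.assign(n + 1, 0);
  C.fp.assign(n + 2, 0);
  C.xpos.assign(n + 1, 0);
  std::vector<int> mp(n + 1, 0);
  for (int i = 0; i < n; ++i) {
    C.code[i + 1] = codes[i];
    C.fp[i + 1] = forced_partner[i];
    C.xpos[i + 1] = forbidden[i] ? 1 : 0;
    mp[i + 1] = forced_partner[i] > 0 ? 1 : 0;
  }
  C.mpcum.assign(n + 1, 0);
  for (int i = 1; i <= n; ++i) C.mpcum[i] = C.mpcum[i - 1] + mp[i];
  for (int a = 0; a < 7; ++a)
    for (int b = 0; b < 7; ++b) C.stack[a][b] = BIG;
  for (int a = 1; a <= 6; ++a)
    for (int b = 1; b <= 6; ++b) {
      double v = stack_tab(a - 1, b - 1);
      C.stack[a][b] = R_finite(v) ? v : BIG;
    }
  C.hairpin.assign(30, BIG);
  C.bulge.assign(30, BIG);
  C.internal_.assign(30, BIG);
  for (int s = 0; s < 30; ++s) {
    if (R_finite(hairpin_tab[s])) C.hairpin[s] = hairpin_tab[s];
    if (R_finite(bulge_tab[s])) C.bulge[s] = bulge_tab[s];
    if (R_finite(internal_tab[s])) C.internal_[s] = internal_tab[s];
  }
  C.extrap = extrapolation;
  C.ninio_slope = ninio[0];
  C.ninio_max = ninio[1];
  C.ml_a = multi[0];
  C.ml_b = multi[1];
  C.ml_c = multi[2];

  if (n == 0) {
    return List::create(_["energy"] = 0.0,
                        _["pairs"] = IntegerMatrix(0, 2),
                        _["feasible"] = true);
  }
  fill_joint(C);
  double e = C.W[n];
  if (e >= BIG / 2) {
    return List::create(_["energy"] = NA_REAL,
                        _["pairs"] = IntegerMatrix(0, 2),
                        _["feasible"] = false);
  }
  std::vector<std::pair<int,int> > pairs;
  traceback(C, pairs);
  std::sort(pairs.begin(), pairs.end());
  IntegerMatrix pm(pairs.size(), 2);
  for (size_t r = 0; r < pairs.size(); ++r) {
    pm(r, 0) = pairs[r].first;
    pm(r, 1) = pairs[r].second;
  }
  return List::create(_["energy"] = e, _["pairs"] = pm,
                      _["feasible"] = true);
}
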