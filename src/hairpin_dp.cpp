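// Banded Needleman-Wunsch over two stem-arms with Nearest-Neighbour
// energy-derived increments, plus the exact motif re-scorer used by the
// genome scan. Bases are encoded A=0, C=1, G=2, U=3, other=-1; canonical
// pairs AU,UA,GC,CG,GU,UG are 0..5 (same order as the R tables).
#include <Rcpp.h>
#include <cmath>
#include <cstring>
#include <vector>
#include <string>
using namespace Rcpp;

struct NNTables {
  double stack[6][6];
  double internal_init[30];
  double bulge_init[30];
  double mm[6][4][4];   // closing pair, strand-1 base, strand-2 base
  double dangle[6][4][2]; // pair, base, side (0 = 5', 1 = 3')
  double asym, ru_closure, ru_end, c_bulge, sym, RT, long_coeff;
};

static inline int pair_id(int x, int y) {
  if (x == 0 && y == 3) return 0; // AU
  if (x == 3 && y == 0) return 1; // UA
  if (x == 2 && y == 1) return 2; // GC
  if (x == 1 && y == 2) return 3; // CG
  if (x == 2 && y == 3) return 4; // GU
  if (x == 3 && y == 2) return 5; // UG
  return -1;
}
static inline int rev_pair(int p) {
  static const int r[6] = {1, 0, 3, 2, 5, 4};
  return r[p];
}
static inline bool is_ru(int p) { return p == 0 || p == 1 || p == 4 || p == 5; }

static NNTables parse_tables(const List& par) {
  NNTables t;
  NumericMatrix st = par["stacking"];
  for (int i = 0; i < 6; ++i)
    for (int j = 0; j < 6; ++j) t.stack[i][j] = st(i, j);
  NumericVector ii = par["internal_init"], bi = par["bulge_init"];
  for (int n = 0; n < 30; ++n) { t.internal_init[n] = ii[n]; t.bulge_init[n] = bi[n]; }
  NumericVector mm = par["terminal_mismatch"]; // dim 6 x 4 x 4
  for (int p = 0; p < 6; ++p)
    for (int x = 0; x < 4; ++x)
      for (int y = 0; y < 4; ++y) t.mm[p][x][y] = mm[p + 6 * (x + 4 * y)];
  NumericVector dg = par["dangle"]; // dim 6 x 4 x 2
  for (int p = 0; p < 6; ++p)
    for (int b = 0; b < 4; ++b)
      for (int s = 0; s < 2; ++s) t.dangle[p][b][s] = dg[p + 6 * (b + 4 * s)];
  t.asym = as<double>(par["asym_penalty"]);
  t.ru_closure = as<double>(par["ru_closure"]);
  t.ru_end = as<double>(par["ru_end"]);
  t.c_bulge = as<double>(par["c_bulge"]);
  t.sym = as<double>(par["sym_correction"]);
  t.RT = as<double>(par["RT"]);
  t.long_coeff = as<double>(par["long_loop_coeff"]);
  return t;
}

static inline double loop_init(const NNTables& t, bool internal, int n) {
  const double* tab = internal ? t.internal_init : t.bulge_init;
  if (n <= 30) return tab[n - 1];
  return tab[29] + t.long_coeff * t.RT * std::log((double)n / 30.0);
}

// ---- alignment DP -------------------------------------------------------
// states: 0 = M (diagonal, canonical pair), 1 = S (diagonal, mismatch),
// 2 = I (gap in arm1, consumes arm2), 3 = D (gap in arm2, consumes arm1)
static const double NEG = -1e18;

struct DPResult { std::string ops; double score; long cells; };

static DPResult dp_align(const int* a1, const int* a2, int l1, int l2,
                         int dw, bool full, const NNTables& t) {
  const int W = l2 + 1;
  const size_t sz = (size_t)(l1 + 1) * W * 4;
  std::vector<double> best(sz, NEG);
  std::vector<signed char> prv(sz, -1); // predecessor state; -2 = origin
  const double s_mis = -t.internal_init[1] / 2.0; // per-step mismatch charge
  const double s_gap = -t.bulge_init[0];          // per-step gap charge
  long cells = 0;
  auto IX = [W](int i, int j, int s) { return ((size_t)i * W + j) * 4 + s; };
  // state preference on equal score: M > S > D > I (diagonal, then D, then I)
  const int pref[4] = {0, 1, 3, 2};

  for (int i = 0; i <= l1; ++i) {
    int jlo = full ? 0 : std::max(0, i - dw);
    int jhi = full ? l2 : std::min(l2, i + dw);
    for (int j = jlo; j <= jhi; ++j) {
      if (i == 0 && j == 0) { ++cells; continue; }
      ++cells;
      // diagonal moves
      if (i > 0 && j > 0 && (full || std::abs((i - 1) - (j - 1)) <= dw)) {
        int p = pair_id(a1[i - 1], a2[j - 1]);
        int tgt = (p >= 0) ? 0 : 1;
        double bs = NEG; signed char bp = -1;
        if (i == 1 && j == 1) { bs = 0.0; bp = -2; }
        for (int k = 0; k < 4; ++k) {
          int s = pref[k];
          double v = best[IX(i - 1, j - 1, s)];
          if (v <= NEG / 2) continue;
          double inc = 0.0;
          if (tgt == 0 && s == 0) {
            int pp = pair_id(a1[i - 2], a2[j - 2]);
            inc = -t.stack[pp][p];
          }
          if (v + inc > bs) { bs = v + inc; bp = (signed char)s; }
        }
        if (bp != -1) {
          double sc = bs + (tgt == 1 ? s_mis : 0.0);
          best[IX(i, j, tgt)] = sc; prv[IX(i, j, tgt)] = bp;
        }
      }
      // D: consume arm1 (gap in arm2)
      if (i > 0 && (full || std::abs((i - 1) - j) <= dw)) {
        double bs = NEG; signed char bp = -1;
        if (i == 1 && j == 0) { bs = 0.0; bp = -2; }
        for (int k = 0; k < 4; ++k) {
          int s = pref[k];
          double v = best[IX(i - 1, j, s)];
          if (v > bs) { bs = v; bp = (signed char)s; }
        }
        if (bs > NEG / 2) { best[IX(i, j, 3)] = bs + s_gap; prv[IX(i, j, 3)] = bp; }
      }
      // I: consume arm2 (gap in arm1)
      if (j > 0 && (full || std::abs(i - (j - 1)) <= dw)) {
        double bs = NEG; signed char bp = -1;
        if (i == 0 && j == 1) { bs = 0.0; bp = -2; }
        for (int k = 0; k < 4; ++k) {
          int s = pref[k];
          double v = best[IX(i, j - 1, s)];
          if (v > bs) { bs = v; bp = (signed char)s; }
        }
        if (bs > NEG / 2) { best[IX(i, j, 2)] = bs + s_gap; prv[IX(i, j, 2)] = bp; }
      }
    }
  }
  // pick final state (diagonal preferred, then D, then I)
  int fs = -1; double fsc = NEG;
  for (int k = 0; k < 4; ++k) {
    int s = pref[k];
    double v = best[IX(l1, l2, s)];
    if (v > fsc) { fsc = v; fs = s; }
  }
  DPResult res; res.cells = cells; res.score = fsc;
  if (fs < 0 || fsc <= NEG / 2) { res.ops = ""; res.score = NA_REAL; return res; }
  // traceback
  std::string ops;
  int i = l1, j = l2, s = fs;
  static const char opc[4] = {'M', 'S', 'I', 'D'};
  while (true) {
    ops.push_back(opc[s]);
    signed char p = prv[IX(i, j, s)];
    if (s == 0 || s == 1) { --i; --j; }
    else if (s == 2) { --j; }
    else { --i; }
    if (p == -2) break;
    s = p;
  }
  std::reverse(ops.begin(), ops.end());
  res.ops = ops;
  return res;
}

// ---- exact motif re-scoring --------------------------------------------
// Mirrors the R reference (decompose_motifs + total_energy): helices from
// maximal M runs; interior non-M runs become internal loops or bulges;
// terminal runs contribute a dangling end when a strand has exactly one
// unpaired base there, and are otherwise unscored.
static double score_ops(const std::string& ops, const int* a1, const int* a2,
                        int l1, int l2, const NNTables& t) {
  const int L = (int)ops.size();
  if (L == 0) return 0.0;
  std::vector<int> xi(L, -1), yi(L, -1);
  int i = 0, j = 0;
  for (int k = 0; k < L; ++k) {
    char c = ops[k];
    if (c == 'M' || c == 'S') { xi[k] = i++; yi[k] = j++; }
    else if (c == 'D') { xi[k] = i++; }
    else { yi[k] = j++; }
  }
  // locate maximal M runs
  std::vector<std::pair<int,int>> mruns;
  for (int k = 0; k < L; ) {
    if (ops[k] == 'M') {
      int s = k;
      while (k < L && ops[k] == 'M') ++k;
      mruns.push_back({s, k - 1});
    } else ++k;
  }
  if (mruns.empty()) return 0.0;
  double E = 0.0;

  // helices
  for (auto& r : mruns) {
    int len = r.second - r.first + 1;
    int p_first = pair_id(a1[xi[r.first]], a2[yi[r.first]]);
    int p_last = pair_id(a1[xi[r.second]], a2[yi[r.second]]);
    for (int k = r.first; k < r.second; ++k) {
      int p1 = pair_id(a1[xi[k]], a2[yi[k]]);
      int p2 = pair_id(a1[xi[k + 1]], a2[yi[k + 1]]);
      E += t.stack[p1][p2];
    }
    bool selfc = true;
    for (int k = 0; k < len; ++k) {
      if (a1[xi[r.first + k]] != a2[yi[r.second - k]]) { selfc = false; break; }
    }
    if (selfc) E += t.sym;
    E += t.ru_end * ((is_ru(p_first) ? 1 : 0) + (is_ru(p_last) ? 1 : 0));
  }

  auto run_counts = [&](int from, int to, int& nx, int& ny,
                        int& x1, int& xl, int& y1, int& yl) {
    nx = ny = 0; x1 = xl = y1 = yl = -1;
    for (int k = from; k <= to; ++k) {
      if (xi[k] >= 0) { if (nx == 0) x1 = xi[k]; xl = xi[k]; ++nx; }
      if (yi[k] >= 0) { if (ny == 0) y1 = yi[k]; yl = yi[k]; ++ny; }
    }
  };
  auto run_len = [](const int* a, int len, int pos) {
    int b = a[pos], n = 1;
    for (int k = pos - 1; k >= 0 && a[k] == b; --k) ++n;
    for (int k = pos + 1; k < len && a[k] == b; ++k) ++n;
    return n;
  };

  // terminal runs: a dangling end is a single unpaired base, so only a
  // run carrying exactly one base (a lone I or D) is scored
  if (mruns.front().first > 0) {
    int nx, ny, x1, xl, y1, yl;
    run_counts(0, mruns.front().first - 1, nx, ny, x1, xl, y1, yl);
    int P = pair_id(a1[xi[mruns.front().first]], a2[yi[mruns.front().first]]);
    if (nx + ny == 1) {
      if (nx == 1) E += t.dangle[P][a1[xl]][0]; // 5' of the top strand
      else E += t.dangle[P][a2[yl]][1];         // 3' of the bottom strand
    }
  }
  if (mruns.back().second < L - 1) {
    int nx, ny, x1, xl, y1, yl;
    run_counts(mruns.back().second + 1, L - 1, nx, ny, x1, xl, y1, yl);
    int P = rev_pair(pair_id(a1[xi[mruns.back().second]],
                             a2[yi[mruns.back().second]]));
    if (nx + ny == 1) {
      if (nx == 1) E += t.dangle[P][a1[x1]][1];
      else E += t.dangle[P][a2[y1]][0];
    }
  }

  // interior runs between consecutive helices
  for (size_t h = 0; h + 1 < mruns.size(); ++h) {
    int from = mruns[h].second + 1, to = mruns[h + 1].first - 1;
    int P5 = pair_id(a1[xi[mruns[h].second]], a2[yi[mruns[h].second]]);
    int P3 = pair_id(a1[xi[mruns[h + 1].first]], a2[yi[mruns[h + 1].first]]);
    int nx, ny, x1, xl, y1, yl;
    run_counts(from, to, nx, ny, x1, xl, y1, yl);
    if (nx > 0 && ny > 0) { // internal loop
      int n = nx + ny;
      E += loop_init(t, true, n);
      E += t.asym * std::abs(nx - ny);
      E += t.mm[P5][a1[x1]][a2[y1]];
      E += t.mm[rev_pair(P3)][a2[yl]][a1[xl]];
      E += t.ru_closure * ((is_ru(P5) ? 1 : 0) + (is_ru(P3) ? 1 : 0));
    } else if (nx > 0 || ny > 0) { // bulge
      int n = nx > 0 ? nx : ny;
      if (n > 1) {
        E += loop_init(t, false, n);
      } else {
        const int* a = nx > 0 ? a1 : a2;
        int alen = nx > 0 ? l1 : l2;
        int pos = nx > 0 ? x1 : y1;
        int b = a[pos];
        int f5 = nx > 0 ? a1[xi[mruns[h].second]] : a2[yi[mruns[h].second]];
        int f3 = nx > 0 ? a1[xi[mruns[h + 1].first]] : a2[yi[mruns[h + 1].first]];
        E += t.bulge_init[0];
        E += t.stack[P5][P3];
        if (b == 1 /*C*/ && (f5 == 1 || f3 == 1)) E += t.c_bulge;
        E -= t.RT * std::log((double)run_len(a, alen, pos));
        E += t.ru_end * ((is_ru(P5) ? 1 : 0) + (is_ru(P3) ? 1 : 0));
      }
    }
  }
  return E;
}

// ---- exported wrappers --------------------------------------------------

// [[Rcpp::export]]
List cpp_align(IntegerVector arm1, IntegerVector arm2, int dw, bool full,
               List params) {
  NNTables t = parse_tables(params);
  int l1 = arm1.size(), l2 = arm2.size();
  std::vector<int> a1(arm1.begin(), arm1.end()), a2(arm2.begin(), arm2.end());
  DPResult r = dp_align(a1.data(), a2.data(), l1, l2, dw, full, t);
  return List::create(_["ops"] = r.ops, _["score"] = r.score,
                      _["cells"] = (double)r.cells);
}

// [[Rcpp::export]]
double cpp_score_ops(std::string ops, IntegerVector arm1, IntegerVector arm2,
                     List params) {
  NNTables t = parse_tables(params);
  std::vector<int> a1(arm1.begin(), arm1.end()), a2(arm2.begin(), arm2.end());
  return score_ops(ops, a1.data(), a2.data(), (int)a1.size(), (int)a2.size(), t);
}

// Scan one strand of one sequence: every window start i and loop length n
// gives arms st1 = seq[i, i+l) and st2 = reverse(seq[i+l+n, i+2l+n)); the
// banded DP aligns them and the exact re-scored energy is thresholded.
// [[Rcpp::export]]
List cpp_scan(IntegerVector seq, int l, int nmin, int nmax, int dw, bool full,
              double threshold, List params) {
  NNTables t = parse_tables(params);
  const int N = seq.size();
  std::vector<int> s(seq.begin(), seq.end());
  std::vector<int> inv(N + 1, 0);
  for (int k = 0; k < N; ++k) inv[k + 1] = inv[k] + (s[k] < 0 || s[k] > 3 ? 1 : 0);
  std::vector<int> a2(l);
  std::vector<int> out_start, out_n;
  std::vector<double> out_E, out_score;
  std::vector<std::string> out_ops;
  long skipped = 0;
  for (int i = 0; i + 2 * l + nmin <= N; ++i) {
    if (inv[i + l] - inv[i] > 0) { // arm1 contains a non-ACGU base
      ++skipped;
      continue;
    }
    for (int n = nmin; n <= nmax && i + 2 * l + n <= N; ++n) {
      int j = i + l + n;
      if (inv[j + l] - inv[j] > 0) { ++skipped; continue; }
      for (int k = 0; k < l; ++k) a2[k] = s[j + l - 1 - k];
      DPResult r = dp_align(&s[i], a2.data(), l, l, dw, full, t);
      if (r.ops.empty()) continue;
      double E = score_ops(r.ops, &s[i], a2.data(), l, l, t);
      if (E <= threshold) {
        out_start.push_back(i); out_n.push_back(n);
        out_E.push_back(E); out_score.push_back(r.score);
        out_ops.push_back(r.ops);
      }
    }
    if (i % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["start"] = out_start, _["n"] = out_n,
                      _["energy"] = out_E, _["dp_score"] = out_score,
                      _["ops"] = out_ops, _["skipped"] = (double)skipped);
}
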