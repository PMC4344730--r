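#include <Rcpp.h>
using namespace Rcpp;

// Shared DP kernels. Base coding throughout: A=0, C=1, G=2, T=3,
// 4 = ambiguity (scores as a mismatch), 5 = masked (unalignable).
// Gap cost convention: a gap of length L costs gap_open + L * gap_extend
// (NCBI-style). Traceback ties resolve diagonal > up > left.

static const double NEG = -1e18;
static const double MASKPEN = -1e9;

inline double subst(int a, int b, double match, double mismatch) {
  if (a == 5 || b == 5) return MASKPEN;
  if (a == 4 || b == 4) return mismatch;
  return (a == b) ? match : mismatch;
}

// ---------------------------------------------------------------------------
// Local (Smith-Waterman) alignment, single best hit, Gotoh H/E/F form.
// H(i,j) = max(0, H(i-1,j-1)+s(i,j), E(i,j), F(i,j))
// E: gap in query (consume subject), F: gap in subject (consume query).
// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(IntegerVector q, IntegerVector s,
                  double match, double mismatch,
                  double gap_open, double gap_extend) {
  int n = q.size(), m = s.size();
  std::vector<double> H((n + 1) * (m + 1), 0.0), E((n + 1) * (m + 1), NEG),
      F((n + 1) * (m + 1), NEG);
  // traceback: tH 0=stop, 1=diag, 2=from F (up), 3=from E (left)
  // tE/tF: 1 = opened from H, 0 = extended
  std::vector<unsigned char> tH((n + 1) * (m + 1), 0),
      tE((n + 1) * (m + 1), 0), tF((n + 1) * (m + 1), 0);
  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int id = i * (m + 1) + j;
      int up = (i - 1) * (m + 1) + j, left = i * (m + 1) + (j - 1),
          diag = (i - 1) * (m + 1) + (j - 1);
      double fo = H[up] - (gap_open + gap_extend), fe = F[up] - gap_extend;
      if (fo >= fe) { F[id] = fo; tF[id] = 1; } else { F[id] = fe; tF[id] = 0; }
      double eo = H[left] - (gap_open + gap_extend), ee = E[left] - gap_extend;
      if (eo >= ee) { E[id] = eo; tE[id] = 1; } else { E[id] = ee; tE[id] = 0; }
      double sc = subst(q[i - 1], s[j - 1], match, mismatch);
      double v = 0.0; unsigned char tb = 0;
      double dg = H[diag] + sc;
      if (dg >= v) { v = dg; tb = 1; }            // prefer diagonal on ties
      if (F[id] > v) { v = F[id]; tb = 2; }
      if (E[id] > v) { v = E[id]; tb = 3; }
      if (v <= 0.0) { v = 0.0; tb = 0; }
      H[id] = v; tH[id] = tb;
      if (v > best) { best = v; bi = i; bj = j; }
    }
  }
  if (best <= 0.0) return List::create(_["score"] = 0.0);
  // traceback from (bi, bj) in H until H traceback says stop
  int i = bi, j = bj;
  int qs = bi, ss = bj;
  int matches = 0, columns = 0;
  int state = 0; // 0 in H, 1 in F (vertical), 2 in E (horizontal)
  while (true) {
    int id = i * (m + 1) + j;
    if (state == 0) {
      unsigned char tb = tH[id];
      if (tb == 0) break;
      if (tb == 1) {
        columns++;
        if (q[i - 1] == s[j - 1] && q[i - 1] < 4) matches++;
        qs = i; ss = j;
        i--; j--;
      } else if (tb == 2) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) { // F: gap in subject, consume query
      columns++;
      qs = i;
      unsigned char tb = tF[id];
      i--;
      state = (tb == 1) ? 0 : 1;
    } else { // E: gap in query, consume subject
      columns++;
      ss = j;
      unsigned char tb = tE[id];
      j--;
      state = (tb == 1) ? 0 : 2;
    }
  }
  return List::create(_["score"] = best, _["q_start"] = qs, _["q_end"] = bi,
                      _["s_start"] = ss, _["s_end"] = bj,
                      _["matches"] = matches, _["columns"] = columns);
}

// ---------------------------------------------------------------------------
// Global affine profile-profile alignment (Needleman-Wunsch with end gaps
// penalized). Profiles are 5 x L matrices of column frequencies over
// {A,C,G,T,gap}. Returns 1-based column index paths (0 = new gap).
// [[Rcpp::export(name = ".nw_profile_cpp")]]
List nw_profile_cpp(NumericMatrix A, NumericMatrix B,
                    double match, double mismatch,
                    double gap_open, double gap_extend) {
  int n = A.ncol(), m = B.ncol();
  std::vector<double> M((n + 1) * (m + 1), NEG), X((n + 1) * (m + 1), NEG),
      Y((n + 1) * (m + 1), NEG);
  std::vector<unsigned char> tM((n + 1) * (m + 1), 0), tX((n + 1) * (m + 1), 0),
      tY((n + 1) * (m + 1), 0);
  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    int id = i * (m + 1);
    X[id] = -(gap_open + gap_extend * i);
    tX[id] = (i == 1) ? 1 : 2;
  }
  for (int j = 1; j <= m; ++j) {
    Y[j] = -(gap_open + gap_extend * j);
    tY[j] = (j == 1) ? 1 : 3;
  }
  // column-pair substitution score
  auto colscore = [&](int i, int j) {
    double sc = 0.0;
    for (int x = 0; x < 4; ++x) {
      double ax = A(x, i - 1);
      if (ax == 0.0) continue;
      for (int y = 0; y < 4; ++y) {
        double by = B(y, j - 1);
        if (by == 0.0) continue;
        sc += ax * by * ((x == y) ? match : mismatch);
      }
    }
    return sc;
  };
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int id = i * (m + 1) + j;
      int up = (i - 1) * (m + 1) + j, left = i * (m + 1) + (j - 1),
          diag = (i - 1) * (m + 1) + (j - 1);
      double xo = M[up] - (gap_open + gap_extend), xe = X[up] - gap_extend;
      if (xo >= xe) { X[id] = xo; tX[id] = 1; } else { X[id] = xe; tX[id] = 2; }
      double yo = M[left] - (gap_open + gap_extend), ye = Y[left] - gap_extend;
      if (yo >= ye) { Y[id] = yo; tY[id] = 1; } else { Y[id] = ye; tY[id] = 3; }
      double sc = colscore(i, j);
      double from = M[diag]; unsigned char tb = 1;
      if (X[diag] > from) { from = X[diag]; tb = 2; }
      if (Y[diag] > from) { from = Y[diag]; tb = 3; }
      M[id] = from + sc; tM[id] = tb;
    }
  }
  int endid = n * (m + 1) + m;
  double sM = M[endid], sX = X[endid], sY = Y[endid];
  // prefer gap-state endings on ties so nested prefixes get end gaps
  int st = 0; double sc = sM;
  if (sX >= sc) { sc = sX; st = 1; }
  if (sY >= sc) { sc = sY; st = 2; }
  // traceback
  std::vector<int> pa, pb;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    int id = i * (m + 1) + j;
    if (st == 0) {
      pa.push_back(i); pb.push_back(j);
      unsigned char tb = tM[id];
      i--; j--;
      st = (tb == 1) ? 0 : (tb == 2 ? 1 : 2);
    } else if (st == 1) {
      pa.push_back(i); pb.push_back(0);
      unsigned char tb = tX[id];
      i--;
      st = (tb == 1) ? 0 : 1;
    } else {
      pa.push_back(0); pb.push_back(j);
      unsigned char tb = tY[id];
      j--;
      st = (tb == 1) ? 0 : 2;
    }
  }
  std::reverse(pa.begin(), pa.end());
  std::reverse(pb.begin(), pb.end());
  return List::create(_["score"] = sc, _["path_a"] = wrap(pa),
                      _["path_b"] = wrap(pb));
}

// ---------------------------------------------------------------------------
// Minimum-free-energy DNA stem-loop (hairpin) within a window.
// Stems are contiguous (no bulges); terminal stem pairs must be matched;
// stacks contribute only between two adjacent matched pairs.
// stack(x1, x2): energy of the dinucleotide step x1->x2 on the top strand.
// [[Rcpp::export(name = ".hairpin_scan_cpp")]]
List hairpin_scan_cpp(IntegerVector s, NumericMatrix stack,
                      int min_stem, int max_stem, int max_mismatch,
                      int min_loop, int max_loop,
                      double loop_init, double loop_per_nt,
                      double mm_penalty) {
  int n = s.size();
  auto comp = [](int x) { return (x < 4) ? 3 - x : -1; };
  double best = R_PosInf;
  int b_i = -1, b_L = 0, b_loop = 0, b_mm = 0;
  for (int i = 0; i < n; ++i) {
    for (int L = min_stem; L <= max_stem; ++L) {
      int e = i + L - 1; // left arm end
      if (e >= n) break;
      for (int loop = min_loop; loop <= max_loop; ++loop) {
        int j = e + 1 + loop; // right arm start
        int jend = j + L - 1;
        if (jend >= n) break;
        // pairing: left k with right (jend - k + i)
        int mm = 0;
        bool ok = true;
        std::vector<bool> m(L);
        for (int k = 0; k < L; ++k) {
          int a = s[i + k], b = s[jend - k];
          bool pair = (a < 4 && b < 4 && a == comp(b));
          m[k] = pair;
          if (!pair) {
            mm++;
            if (k == 0 || k == L - 1 || mm > max_mismatch) { ok = false; break; }
          }
        }
        if (!ok) continue;
        double dg = loop_init + loop_per_nt * (loop - min_loop) +
                    mm_penalty * mm;
        for (int k = 0; k + 1 < L; ++k)
          if (m[k] && m[k + 1]) dg += stack(s[i + k], s[i + k + 1]);
        if (dg < best) {
          best = dg; b_i = i; b_L = L; b_loop = loop; b_mm = mm;
        }
      }
    }
  }
  if (b_i < 0) return List::create(_["found"] = false);
  return List::create(_["found"] = true, _["dg"] = best,
                      _["left_start"] = b_i + 1, _["left_end"] = b_i + b_L,
                      _["right_start"] = b_i + b_L + b_loop + 1,
                      _["right_end"] = b_i + 2 * b_L + b_loop,
                      _["loop_len"] = b_loop, _["mismatches"] = b_mm);
}

// ---------------------------------------------------------------------------
// Maximal inverted-repeat runs. For element positions p < q, p pairs with q
// when s[p] is the Watson-Crick complement of s[q]; runs live on
// anti-diagonals p + q = d. Reports maximal runs with <= max_mismatch
// mismatches, arm length >= min_arm, terminal positions matched, and at
// least min_sep unpaired bases between the arms. 1-based coordinates.
// [[Rcpp::export(name = ".ir_runs_cpp")]]
DataFrame ir_runs_cpp(IntegerVector s, int min_arm, int max_mismatch,
                      int min_sep) {
  int n = s.size();
  auto comp = [](int x) { return (x < 4) ? 3 - x : -1; };
  std::vector<int> a_start, a_end, b_start, b_end, arm_len, mism;
  for (int d = 0; d <= 2 * (n - 1); ++d) {
    // positions p with p < d - p (strict), both in range
    int plo = std::max(0, d - (n - 1));
    int phi = (d - min_sep - 1) / 2; // ensure q - p - 1 >= min_sep when run ends at p
    if (phi < plo) continue;
    int len = phi - plo + 1;
    // match vector along the diagonal
    std::vector<bool> mt(len);
    for (int t = 0; t < len; ++t) {
      int p = plo + t, q = d - p;
      mt[t] = (s[p] < 4 && s[q] < 4 && s[p] == comp(s[q]));
    }
    // two-pointer maximal windows with <= max_mismatch mismatches,
    // trimmed to matched endpoints
    int lo = 0;
    int mm = 0;
    for (int hi = 0; hi < len; ++hi) {
      if (!mt[hi]) mm++;
      while (mm > max_mismatch) { if (!mt[lo]) mm--; lo++; }
      // window [lo, hi] is feasible; report only right-maximal windows
      bool right_max = (hi == len - 1) || (!mt[hi + 1] && mm == max_mismatch);
      if (!right_max) continue;
      int L = lo, H = hi;
      while (L <= H && !mt[L]) L++;
      while (H >= L && !mt[H]) H--;
      if (H - L + 1 < min_arm) continue;
      // left-maximality after trimming: if a longer feasible window with the
      // same right end exists it was covered by a smaller lo; accept as-is.
      int p1 = plo + L, p2 = plo + H;
      int q1 = d - p2, q2 = d - p1;
      if (q1 - p2 - 1 < min_sep) continue;
      int nmm = 0;
      for (int t = L; t <= H; ++t) if (!mt[t]) nmm++;
      // drop duplicates (same run reported twice)
      bool dup = false;
      for (size_t r = 0; r < a_start.size(); ++r)
        if (a_start[r] == p1 + 1 && a_end[r] == p2 + 1 &&
            b_start[r] == q1 + 1) { dup = true; break; }
      if (dup) continue;
      a_start.push_back(p1 + 1); a_end.push_back(p2 + 1);
      b_start.push_back(q1 + 1); b_end.push_back(q2 + 1);
      arm_len.push_back(p2 - p1 + 1); mism.push_back(nmm);
    }
  }
  return DataFrame::create(_["a_start"] = a_start, _["a_end"] = a_end,
                           _["b_start"] = b_start, _["b_end"] = b_end,
                           _["arm_len"] = arm_len, _["mismatches"] = mism);
}
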