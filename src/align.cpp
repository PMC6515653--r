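#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap local alignment (Smith-Waterman, three-state DP).
// Sequences arrive as 0-based integer codes into the substitution matrix.
// Gap cost convention: a gap of length L costs gap_open + L * gap_ext
// (the first gapped residue pays gap_open + gap_ext).
//
// [[Rcpp::export]]
List sw_align_cpp(IntegerVector q, IntegerVector s, NumericMatrix submat,
                  double gap_open, double gap_ext) {
  const int m = q.size(), n = s.size();
  const double NEG = -1e30;
  if (m == 0 || n == 0) {
    return List::create(_["score"] = 0.0,
                        _["q_start"] = 0, _["q_end"] = 0,
                        _["s_start"] = 0, _["s_end"] = 0);
  }
  // H: best score ending at (i,j) in match state; E: gap in query (consume s);
  // F: gap in subject (consume q). Rolling rows for H/E; full traceback
  // matrices kept (desk-scale sequences).
  std::vector<double> Hprev(n + 1, 0.0), Hcur(n + 1, 0.0);
  std::vector<double> Eprev(n + 1, NEG), Ecur(n + 1, NEG);
  std::vector<double> Fcol(n + 1, NEG);
  // tb codes per cell: 0 stop, 1 diag, 2 left(E), 3 up(F); separate state
  // trace for E/F extension.
  std::vector<signed char> tbH((m + 1) * (n + 1), 0);
  std::vector<signed char> tbE((m + 1) * (n + 1), 0); // 1 = opened here
  std::vector<signed char> tbF((m + 1) * (n + 1), 0);
  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    Hcur[0] = 0.0; Ecur[0] = NEG; Fcol[0] = NEG;
    double Fdiag; // F for current column tracked in Fcol
    (void)Fdiag;
    for (int j = 1; j <= n; ++j) {
      size_t idx = (size_t)i * (n + 1) + j;
      double e_open = Hcur[j - 1] - (gap_open + gap_ext);
      double e_ext  = Ecur[j - 1] - gap_ext;
      double E = std::max(e_open, e_ext);
      tbE[idx] = (e_open >= e_ext) ? 1 : 0;
      double f_open = Hprev[j] - (gap_open + gap_ext);
      double f_ext  = Fcol[j] - gap_ext;
      double F = std::max(f_open, f_ext);
      tbF[idx] = (f_open >= f_ext) ? 1 : 0;
      double diag = Hprev[j - 1] + submat(q[i - 1], s[j - 1]);
      double H = 0.0; signed char tb = 0;
      if (diag > H) { H = diag; tb = 1; }
      if (E > H)    { H = E;    tb = 2; }
      if (F > H)    { H = F;    tb = 3; }
      Hcur[j] = H; Ecur[j] = E; Fcol[j] = F; tbH[idx] = tb;
      if (H > best) { best = H; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur); std::swap(Eprev, Ecur);
  }
  if (best <= 0.0) {
    return List::create(_["score"] = 0.0,
                        _["q_start"] = 0, _["q_end"] = 0,
                        _["s_start"] = 0, _["s_end"] = 0);
  }
  // traceback from (bi,bj) in H state
  int i = bi, j = bj, state = 0; // 0=H, 1=E, 2=F
  int qs = bi, ss = bj;
  while (i > 0 && j > 0) {
    size_t idx = (size_t)i * (n + 1) + j;
    if (state == 0) {
      signed char tb = tbH[idx];
      if (tb == 0) break;
      if (tb == 1) { qs = i; ss = j; --i; --j; }
      else if (tb == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      signed char opened = tbE[idx];
      ss = j; --j;
      if (opened) state = 0;
    } else {
      signed char opened = tbF[idx];
      qs = i; --i;
      if (opened) state = 0;
    }
  }
  return List::create(_["score"] = best,
                      _["q_start"] = qs, _["q_end"] = bi,
                      _["s_start"] = ss, _["s_end"] = bj);
}

// Global affine-gap alignment path over a precomputed column-pair score
// matrix S (rows = columns of profile 1, cols = columns of profile 2).
// Returns a vector of moves: 1 = aligned column pair, 2 = column from
// profile 1 against gap, 3 = column from profile 2 against gap.
//
// [[Rcpp::export]]
IntegerVector nw_profile_path_cpp(NumericMatrix S, double gap_open,
                                  double gap_ext) {
  const int m = S.nrow(), n = S.ncol();
  const double NEG = -1e30;
  std::vector<double> M((m + 1) * (n + 1), NEG);
  std::vector<double> X((m + 1) * (n + 1), NEG); // gap in profile2 (consume 1)
  std::vector<double> Y((m + 1) * (n + 1), NEG); // gap in profile1 (consume 2)
  auto at = [n](int i, int j) { return (size_t)i * (n + 1) + j; };
  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= m; ++i)
    X[at(i, 0)] = -(gap_open + gap_ext) - gap_ext * (i - 1);
  for (int j = 1; j <= n; ++j)
    Y[at(0, j)] = -(gap_open + gap_ext) - gap_ext * (j - 1);
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      double mm = std::max(M[at(i-1,j-1)], std::max(X[at(i-1,j-1)], Y[at(i-1,j-1)]));
      M[at(i, j)] = mm + S(i - 1, j - 1);
      X[at(i, j)] = std::max(M[at(i-1,j)] - (gap_open + gap_ext),
                             std::max(X[at(i-1,j)] - gap_ext,
                                      Y[at(i-1,j)] - (gap_open + gap_ext)));
      Y[at(i, j)] = std::max(M[at(i,j-1)] - (gap_open + gap_ext),
                             std::max(Y[at(i,j-1)] - gap_ext,
                                      X[at(i,j-1)] - (gap_open + gap_ext)));
    }
  }
  // traceback, preferring aligned pairs on ties for compact alignments
  std::vector<int> rev;
  int i = m, j = n, state;
  {
    double vm = M[at(m, n)], vx = X[at(m, n)], vy = Y[at(m, n)];
    state = (vm >= vx && vm >= vy) ? 0 : (vx >= vy ? 1 : 2);
  }
  const double tol = 1e-9;
  while (i > 0 || j > 0) {
    if (i == 0) { rev.push_back(3); --j; continue; }
    if (j == 0) { rev.push_back(2); --i; continue; }
    if (state == 0) {
      rev.push_back(1);
      double prev = M[at(i, j)] - S(i - 1, j - 1);
      --i; --j;
      if (std::fabs(M[at(i, j)] - prev) < tol) state = 0;
      else if (std::fabs(X[at(i, j)] - prev) < tol) state = 1;
      else state = 2;
    } else if (state == 1) {
      rev.push_back(2);
      double cur = X[at(i, j)];
      --i;
      if (std::fabs(M[at(i, j)] - (gap_open + gap_ext) - cur) < tol) state = 0;
      else if (std::fabs(X[at(i, j)] - gap_ext - cur) < tol) state = 1;
      else state = 2;
    } else {
      rev.push_back(3);
      double cur = Y[at(i, j)];
      --j;
      if (std::fabs(M[at(i, j)] - (gap_open + gap_ext) - cur) < tol) state = 0;
      else if (std::fabs(Y[at(i, j)] - gap_ext - cur) < tol) state = 2;
      else state = 1;
    }
  }
  std::reverse(rev.begin(), rev.end());
  return wrap(rev);
}

// Score-only Smith-Waterman over all query x subject pairs (no traceback;
// rolling arrays). Used by the screening stages, where only best scores
// matter and the pair count is large.
//
// [[Rcpp::export]]
NumericMatrix sw_score_matrix_cpp(List qs, List ss, NumericMatrix submat,
                                  double gap_open, double gap_ext) {
  const int nq = qs.size(), ns = ss.size();
  const double NEG = -1e30;
  NumericMatrix out(nq, ns);
  std::vector<std::vector<int>> qv(nq), sv(ns);
  for (int i = 0; i < nq; ++i) qv[i] = as<std::vector<int>>(qs[i]);
  for (int j = 0; j < ns; ++j) sv[j] = as<std::vector<int>>(ss[j]);
  for (int a = 0; a < nq; ++a) {
    const std::vector<int>& q = qv[a];
    const int m = (int)q.size();
    for (int b = 0; b < ns; ++b) {
      const std::vector<int>& s = sv[b];
      const int n = (int)s.size();
      if (m == 0 || n == 0) { out(a, b) = 0.0; continue; }
      std::vector<double> Hprev(n + 1, 0.0), Hcur(n + 1, 0.0);
      std::vector<double> Eprev(n + 1, NEG), Ecur(n + 1, NEG);
      std::vector<double> Fcol(n + 1, NEG);
      double best = 0.0;
      for (int i = 1; i <= m; ++i) {
        Hcur[0] = 0.0; Ecur[0] = NEG;
        const double* srow = &submat(q[i - 1], 0);
        const int nrow = submat.nrow();
        for (int j = 1; j <= n; ++j) {
          double E = std::max(Hcur[j - 1] - (gap_open + gap_ext),
                              Ecur[j - 1] - gap_ext);
          double F = std::max(Hprev[j] - (gap_open + gap_ext),
                              Fcol[j] - gap_ext);
          double diag = Hprev[j - 1] + srow[(size_t)s[j - 1] * nrow];
          double H = 0.0;
          if (diag > H) H = diag;
          if (E > H) H = E;
          if (F > H) H = F;
          Hcur[j] = H; Ecur[j] = E; Fcol[j] = F;
          if (H > best) best = H;
        }
        std::swap(Hprev, Hcur); std::swap(Eprev, Ecur);
      }
      out(a, b) = best;
    }
  }
  return out;
}
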