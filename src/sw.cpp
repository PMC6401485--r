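#include <Rcpp.h>
using namespace Rcpp;

// Local (Smith-Waterman) alignment with affine gaps and full traceback.
//
// q, s: 1-based integer-encoded residues (indices into the rows/cols of smat).
// smat: substitution score matrix. A gap of length L costs
// gap_open + L*gap_extend (same convention as Biostrings::pairwiseAlignment).
//
// Returns the single best-scoring local alignment; ties are resolved
// deterministically (earliest end cell in row-major order; diagonal moves
// preferred during traceback).
// [[Rcpp::export(name = ".sw_align_int")]]
List sw_align_int(IntegerVector q, IntegerVector s, IntegerMatrix smat,
                  int gap_open, int gap_extend) {
  const int nq = q.size(), ns = s.size();
  const int NEG = INT_MIN / 4;
  const int gfirst = gap_open + gap_extend;

  std::vector<int> Mprev(ns + 1, 0), Mcur(ns + 1, 0);
  std::vector<int> Xprev(ns + 1, NEG), Xcur(ns + 1, NEG);
  std::vector<int> Yprev(ns + 1, NEG), Ycur(ns + 1, NEG);
  // traceback: tbM 0=fresh start, 1=from M, 2=from X, 3=from Y
  //            tbX 1=open (from M above), 2=extend; tbY likewise (from left)
  std::vector<unsigned char> tbM((size_t)(nq + 1) * (ns + 1), 0);
  std::vector<unsigned char> tbX((size_t)(nq + 1) * (ns + 1), 0);
  std::vector<unsigned char> tbY((size_t)(nq + 1) * (ns + 1), 0);

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= nq; ++i) {
    Mcur[0] = 0; Xcur[0] = NEG; Ycur[0] = NEG;
    const int qi = q[i - 1] - 1;
    for (int j = 1; j <= ns; ++j) {
      const size_t at = (size_t)i * (ns + 1) + j;
      // X: gap in subject (consume query residue i)
      int xo = Mprev[j] - gfirst, xe = Xprev[j] - gap_extend;
      if (xo >= xe) { Xcur[j] = xo; tbX[at] = 1; } else { Xcur[j] = xe; tbX[at] = 2; }
      // Y: gap in query (consume subject residue j)
      int yo = Mcur[j - 1] - gfirst, ye = Ycur[j - 1] - gap_extend;
      if (yo >= ye) { Ycur[j] = yo; tbY[at] = 1; } else { Ycur[j] = ye; tbY[at] = 2; }
      // M: aligned pair
      int sub = smat(qi, s[j - 1] - 1);
      int fm = Mprev[j - 1], fx = Xprev[j - 1], fy = Yprev[j - 1];
      int from = fm; unsigned char st = 1;
      if (fx > from) { from = fx; st = 2; }
      if (fy > from) { from = fy; st = 3; }
      if (from <= 0) { from = 0; st = 0; }
      Mcur[j] = sub + from;
      tbM[at] = st;
      if (Mcur[j] > best) { best = Mcur[j]; bi = i; bj = j; }
    }
    std::swap(Mprev, Mcur); std::swap(Xprev, Xcur); std::swap(Yprev, Ycur);
  }

  if (best <= 0)
    return List::create(_["score"] = 0, _["q_start"] = 0, _["q_end"] = 0,
                        _["s_start"] = 0, _["s_end"] = 0, _["identities"] = 0,
                        _["mismatches"] = 0, _["gap_openings"] = 0,
                        _["align_len"] = 0);

  // traceback
  int i = bi, j = bj, state = 1; // end in M by construction
  int ident = 0, mism = 0, gapopen = 0, alen = 0;
  int qe = bi, se = bj, qs = bi, ss = bj;
  bool done = false;
  while (!done) {
    const size_t at = (size_t)i * (ns + 1) + j;
    if (state == 1) {
      alen++;
      if (q[i - 1] == s[j - 1]) ident++; else mism++;
      qs = i; ss = j;
      unsigned char st = tbM[at];
      i--; j--;
      if (st == 0) done = true; else state = st;
    } else if (state == 2) {
      alen++;
      unsigned char st = tbX[at];
      if (st == 1) { gapopen++; state = 1; } // gap run starts here
      i--;
    } else {
      alen++;
      unsigned char st = tbY[at];
      if (st == 1) { gapopen++; state = 1; }
      j--;
    }
  }

  return List::create(_["score"] = best,
                      _["q_start"] = qs - 1, _["q_end"] = qe,
                      _["s_start"] = ss - 1, _["s_end"] = se,
                      _["identities"] = ident, _["mismatches"] = mism,
                      _["gap_openings"] = gapopen, _["align_len"] = alen);
}
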