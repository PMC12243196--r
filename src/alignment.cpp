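#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <limits>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment under match=1 / mismatch=0 / linear gap
// cost per gapped position. Among score-optimal alignments the one with the
// largest number of identical pairs is taken, so the reported identity
// numerator is deterministic. Score and match count are packed into one
// double key (score * 2^20 + matches) so the lexicographic maximum is a
// single comparison; exact because both parts are small integers (gap_cost
// is scaled to an integer grid of 1/64ths).
// [[Rcpp::export(name = ".nw_identity_matches")]]
int nw_identity_matches(std::string a, std::string b, double gap_cost) {
  const int la = a.size(), lb = b.size();
  const double G = std::round(gap_cost * 64.0);       // score unit = 1/64
  const double M = 64.0;
  const double KEY = 1048576.0;                        // 2^20 > max matches
  const double GK = G * KEY, MK = M * KEY + 1.0;
  std::vector<double> prev(lb + 1), cur(lb + 1);
  for (int j = 0; j <= lb; ++j) prev[j] = -GK * j;
  for (int i = 1; i <= la; ++i) {
    cur[0] = -GK * i;
    const char ai = a[i - 1];
    for (int j = 1; j <= lb; ++j) {
      double diag = prev[j - 1] + (ai == b[j - 1] ? MK : 0.0);
      double gap = std::max(prev[j], cur[j - 1]) - GK;
      cur[j] = std::max(diag, gap);
    }
    std::swap(prev, cur);
  }
  return (int)(prev[lb] - KEY * std::floor(prev[lb] / KEY) + 0.5) % (int)KEY;
}

// Smith-Waterman local alignment with affine gaps (Gotoh). A gap of length k
// costs gap_open + k * gap_extend (BLAST convention). ai/bi are 1-based
// indices into the substitution matrix. Traceback prefers diagonal, then a
// gap in the query, then a gap in the subject, making the reported span
// deterministic.
// [[Rcpp::export(name = ".sw_align")]]
List sw_align(IntegerVector ai, IntegerVector bi, NumericMatrix submat,
              double gap_open, double gap_extend) {
  const int m = ai.size(), n = bi.size();
  const int ncol = submat.nrow();
  const double NEG = -std::numeric_limits<double>::infinity();
  const double open_cost = gap_open + gap_extend;
  std::vector<double> sub(submat.begin(), submat.end());
  std::vector<double> Hp(n + 1, 0.0), Hc(n + 1, 0.0), Ep(n + 1, NEG),
      Ec(n + 1, NEG), Fp(n + 1, NEG), Fc(n + 1, NEG);
  // traceback codes per cell: H: 0 stop, 1 diag, 2 from E, 3 from F;
  // E/F: 0 opened, 1 extended. Packed as TH + 4*TE + 8*TF.
  std::vector<uint8_t> tb((size_t)(m + 1) * (n + 1), 0);
  double best = 0.0; int bi_r = 0, bj_r = 0;
  for (int i = 1; i <= m; ++i) {
    Hc[0] = 0.0; Ec[0] = NEG; Fc[0] = NEG;
    const double *srow = &sub[(size_t)(ai[i - 1] - 1)];
    uint8_t *trow = &tb[(size_t)i * (n + 1)];
    for (int j = 1; j <= n; ++j) {
      double e_open = Hc[j - 1] - open_cost, e_ext = Ec[j - 1] - gap_extend;
      double e = std::max(e_open, e_ext);
      uint8_t te = e_ext > e_open;
      double f_open = Hp[j] - open_cost, f_ext = Fp[j] - gap_extend;
      double f = std::max(f_open, f_ext);
      uint8_t tf = f_ext > f_open;
      double diag = Hp[j - 1] + srow[(size_t)(bi[j - 1] - 1) * ncol];
      double h = std::max(std::max(diag, 0.0), std::max(e, f));
      uint8_t th = (h <= 0.0) ? 0 : (diag >= h ? 1 : (e >= h ? 2 : 3));
      Ec[j] = e; Fc[j] = f; Hc[j] = h;
      trow[j] = th | (te << 2) | (tf << 3);
      if (h > best) { best = h; bi_r = i; bj_r = j; }
    }
    std::swap(Hp, Hc); std::swap(Ep, Ec); std::swap(Fp, Fc);
  }
  int matches = 0, mismatches = 0, gapopens = 0, aln_len = 0;
  int qend = bi_r, send = bj_r, qstart = 0, sstart = 0;
  if (best > 0.0) {
    int i = bi_r, j = bj_r, state = 0;  // 0 = H, 1 = E (gap in query), 2 = F
    while (i > 0 && j > 0) {
      uint8_t code = tb[(size_t)i * (n + 1) + j];
      if (state == 0) {
        uint8_t th = code & 3;
        if (th == 0) break;
        if (th == 1) {
          ++aln_len;
          if (ai[i - 1] == bi[j - 1]) ++matches; else ++mismatches;
          qstart = i; sstart = j; --i; --j;
        } else if (th == 2) { state = 1; ++gapopens; }
        else { state = 2; ++gapopens; }
      } else if (state == 1) {
        ++aln_len;
        state = ((code >> 2) & 1) ? 1 : 0;
        --j;
      } else {
        ++aln_len;
        state = ((code >> 3) & 1) ? 2 : 0;
        --i;
      }
    }
  } else {
    qend = 0; send = 0;
  }
  return List::create(
    _["score"] = best, _["qstart"] = qstart, _["qend"] = qend,
    _["sstart"] = sstart, _["send"] = send, _["matches"] = matches,
    _["mismatches"] = mismatches, _["gapopens"] = gapopens,
    _["aln_length"] = aln_len);
}
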