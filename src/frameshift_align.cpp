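// Frameshift-tolerant alignment of a reference protein against a
// nucleotide locus: dynamic programming over (reference residue, locus
// nucleotide) where a residue may consume 3 nt (in-frame codon), 2 nt
// (single-base deletion in the locus) or 4 nt (single-base insertion),
// the latter two paying a frame-jump penalty.  The protein is aligned
// globally, the locus ends are free.

#include <Rcpp.h>
using namespace Rcpp;

static inline int nt_index(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default: return -1;
  }
}

// [[Rcpp::export(name = ".frameshift_align_cpp")]]
List frameshift_align_cpp(std::string ref, std::string nt,
                          NumericMatrix sub, std::string alphabet,
                          std::string codon_aa,
                          double fs_penalty, double gap_aa,
                          double gap_codon) {
  const int m = ref.size();
  const int n = nt.size();
  const double NEG = -1e9;

  // residue -> row index of the substitution matrix
  std::vector<int> aa_idx(256, -1);
  for (size_t i = 0; i < alphabet.size(); ++i)
    aa_idx[(unsigned char)alphabet[i]] = (int)i;
  int x_idx = aa_idx[(unsigned char)'X'];

  // amino acid encoded at codon ending at nt position j (1-based), or
  // 'X' when the codon contains a non-ACGT symbol
  std::vector<int> codon_at(n + 1, x_idx);   // aa index of nt[j-3..j-1]
  std::vector<bool> stop_at(n + 1, false);
  for (int j = 3; j <= n; ++j) {
    int a = nt_index(nt[j - 3]), b = nt_index(nt[j - 2]),
        c = nt_index(nt[j - 1]);
    if (a >= 0 && b >= 0 && c >= 0) {
      char aa = codon_aa[16 * a + 4 * b + c];
      stop_at[j] = (aa == '*');
      int idx = aa_idx[(unsigned char)aa];
      codon_at[j] = idx >= 0 ? idx : x_idx;
    }
  }

  std::vector<int> ref_idx(m);
  for (int i = 0; i < m; ++i) {
    int idx = aa_idx[(unsigned char)ref[i]];
    ref_idx[i] = idx >= 0 ? idx : x_idx;
  }

  NumericMatrix dp(m + 1, n + 1);
  IntegerMatrix tb(m + 1, n + 1);  // 0 none, 1 diag3, 2 fs2, 3 fs4,
                                   // 4 del_aa, 5 ins_codon
  for (int j = 0; j <= n; ++j) dp(0, j) = 0.0;
  for (int i = 1; i <= m; ++i) { dp(i, 0) = dp(i - 1, 0) - gap_aa;
                                 tb(i, 0) = 4; }

  for (int i = 1; i <= m; ++i) {
    const int ri = ref_idx[i - 1];
    for (int j = 1; j <= n; ++j) {
      double best = dp(i - 1, j) - gap_aa;
      int move = 4;
      if (j >= 3) {
        double s = dp(i - 1, j - 3) + sub(ri, codon_at[j]);
        if (s > best) { best = s; move = 1; }
        double t = dp(i, j - 3) - gap_codon;
        if (t > best) { best = t; move = 5; }
      }
      if (j >= 2) {
        double s = dp(i - 1, j - 2) - fs_penalty + sub(ri, x_idx);
        if (s > best) { best = s; move = 2; }
      }
      if (j >= 4) {
        double s = dp(i - 1, j - 4) - fs_penalty + sub(ri, codon_at[j]);
        if (s > best) { best = s; move = 3; }
      }
      dp(i, j) = best;
      tb(i, j) = move;
    }
  }

  // free trailing nucleotides: best cell in the last row
  int j_end = 0;
  double best = NEG;
  for (int j = 0; j <= n; ++j) {
    if (dp(m, j) > best) { best = dp(m, j); j_end = j; }
  }

  // traceback
  std::vector<int> mv, iv, jv;
  std::string qaln, saln;
  int i = m, j = j_end;
  while (i > 0) {
    int move = tb(i, j);
    mv.push_back(move); iv.push_back(i); jv.push_back(j);
    switch (move) {
    case 1:
      qaln += ref[i - 1];
      saln += stop_at[j] ? '*' : alphabet[codon_at[j]];
      i -= 1; j -= 3; break;
    case 2:
      qaln += ref[i - 1]; saln += '!';
      i -= 1; j -= 2; break;
    case 3:
      qaln += ref[i - 1];
      saln += stop_at[j] ? '*' : alphabet[codon_at[j]];
      i -= 1; j -= 4; break;
    case 4:
      qaln += ref[i - 1]; saln += '-';
      i -= 1; break;
    case 5:
      qaln += '-';
      saln += stop_at[j] ? '*' : alphabet[codon_at[j]];
      j -= 3; break;
    default:
      stop("corrupt traceback");
    }
  }
  int j_start = j;  // leading nt [1..j_start] unaligned
  std::reverse(qaln.begin(), qaln.end());
  std::reverse(saln.begin(), saln.end());
  std::reverse(mv.begin(), mv.end());
  std::reverse(iv.begin(), iv.end());
  std::reverse(jv.begin(), jv.end());

  // stop codons consumed by the alignment
  std::vector<int> stop_j, stop_i;
  for (size_t k = 0; k < mv.size(); ++k) {
    if ((mv[k] == 1 || mv[k] == 3 || mv[k] == 5) && stop_at[jv[k]]) {
      stop_j.push_back(jv[k]);
      stop_i.push_back(iv[k]);
    }
  }

  return List::create(
    _["score"] = best,
    _["nt_start"] = j_start + 1,
    _["nt_end"] = j_end,
    _["moves"] = IntegerVector(mv.begin(), mv.end()),
    _["ref_pos"] = IntegerVector(iv.begin(), iv.end()),
    _["nt_pos"] = IntegerVector(jv.begin(), jv.end()),
    _["stop_nt"] = IntegerVector(stop_j.begin(), stop_j.end()),
    _["stop_ref"] = IntegerVector(stop_i.begin(), stop_i.end()),
    _["qaln"] = qaln,
    _["saln"] = saln);
}
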