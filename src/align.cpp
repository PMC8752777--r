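#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
#include <limits>
using namespace Rcpp;

// Global (Needleman-Wunsch-Gotoh) alignment with affine gaps.
// A gap of length L costs gap_open + L * gap_extend.
// Returns score, CIGAR over {M, I, D} (I = insertion in the read relative
// to the reference), and the mismatch count along M columns.
// Traceback uses explicit pointers laid down during the fill; ties prefer
// M, then D, then I. Indel placement is canonicalized by left-alignment
// downstream, so traceback tie order does not affect reported events.
// [[Rcpp::export(name = ".affine_align_cpp")]]
List affine_align_cpp(std::string a, std::string b,
                      double match, double mismatch,
                      double gap_open, double gap_extend) {
  const int n = (int)a.size();   // read segment
  const int m = (int)b.size();   // reference segment
  const double NEG = -1e30;
  const double go = gap_open + gap_extend;  // cost of a length-1 gap

  std::vector<double> M((n + 1) * (m + 1), NEG);
  std::vector<double> I((n + 1) * (m + 1), NEG);  // gap in b, consumes a
  std::vector<double> D((n + 1) * (m + 1), NEG);  // gap in a, consumes b
  std::vector<char> tbM((n + 1) * (m + 1), 0);
  std::vector<char> tbI((n + 1) * (m + 1), 0);
  std::vector<char> tbD((n + 1) * (m + 1), 0);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) {
    I[at(i, 0)] = -(gap_open + i * gap_extend);
    tbI[at(i, 0)] = (i == 1) ? 'M' : 'I';
  }
  for (int j = 1; j <= m; ++j) {
    D[at(0, j)] = -(gap_open + j * gap_extend);
    tbD[at(0, j)] = (j == 1) ? 'M' : 'D';
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = (a[i - 1] == b[j - 1] && a[i - 1] != 'N') ? match : mismatch;
      // M: diagonal from the best of M/D/I (prefer M, then D, then I).
      double pM = M[at(i - 1, j - 1)], pD = D[at(i - 1, j - 1)],
             pI = I[at(i - 1, j - 1)];
      double bestp = pM; char st = 'M';
      if (pD > bestp) { bestp = pD; st = 'D'; }
      if (pI > bestp) { bestp = pI; st = 'I'; }
      if (bestp > NEG / 2) { M[at(i, j)] = bestp + s; tbM[at(i, j)] = st; }
      // I: vertical (consume read base).
      double oM = M[at(i - 1, j)] - go, oD = D[at(i - 1, j)] - go,
             eI = I[at(i - 1, j)] - gap_extend;
      double bi = oM; char sti = 'M';
      if (oD > bi) { bi = oD; sti = 'D'; }
      if (eI > bi) { bi = eI; sti = 'I'; }
      I[at(i, j)] = bi; tbI[at(i, j)] = sti;
      // D: horizontal (consume reference base).
      double hM = M[at(i, j - 1)] - go, hI = I[at(i, j - 1)] - go,
             eD = D[at(i, j - 1)] - gap_extend;
      double bd = hM; char std_ = 'M';
      if (eD > bd) { bd = eD; std_ = 'D'; }
      if (hI > bd) { bd = hI; std_ = 'I'; }
      D[at(i, j)] = bd; tbD[at(i, j)] = std_;
    }
  }

  double sM = M[at(n, m)], sI = I[at(n, m)], sD = D[at(n, m)];
  double score = sM; char state = 'M';
  if (sD > score) { score = sD; state = 'D'; }
  if (sI > score) { score = sI; state = 'I'; }
  if (n == 0 && m == 0) { score = 0.0; state = 'M'; }

  // Traceback.
  std::string ops;
  int i = n, j = m;
  int mismatches = 0;
  while (i > 0 || j > 0) {
    if (state == 'M') {
      if (a[i - 1] != b[j - 1] || a[i - 1] == 'N') ++mismatches;
      ops.push_back('M');
      char prev = tbM[at(i, j)];
      --i; --j;
      state = prev;
    } else if (state == 'I') {
      ops.push_back('I');
      char prev = tbI[at(i, j)];
      --i;
      state = prev;
    } else {
      ops.push_back('D');
      char prev = tbD[at(i, j)];
      --j;
      state = prev;
    }
  }
  std::reverse(ops.begin(), ops.end());

  // Run-length encode into a CIGAR string.
  std::string cigar;
  size_t k = 0;
  while (k < ops.size()) {
    size_t r = k;
    while (r < ops.size() && ops[r] == ops[k]) ++r;
    cigar += std::to_string(r - k);
    cigar.push_back(ops[k]);
    k = r;
  }

  return List::create(_["score"] = score, _["cigar"] = cigar,
                      _["n_mismatch"] = mismatches);
}
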