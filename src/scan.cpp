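#include <Rcpp.h>
using namespace Rcpp;

// Window scores for a PWM over an integer-coded sequence (A=0,C=1,G=2,T=3,
// N/other=4). Scores are discretized integers; windows containing an
// ambiguous base score NA. Returns a list of forward- and reverse-strand
// score vectors, one entry per window start.

// [[Rcpp::export]]
List scan_pwm_codes(IntegerVector codes, IntegerMatrix fwd, IntegerMatrix rev) {
  const int n = codes.size();
  const int w = fwd.nrow();
  const int nwin = n - w + 1;
  if (nwin <= 0) return List::create(IntegerVector(0), IntegerVector(0));
  IntegerVector sf(nwin), sr(nwin);
  for (int i = 0; i < nwin; ++i) {
    int accf = 0, accr = 0;
    bool ok = true;
    for (int j = 0; j < w; ++j) {
      const int b = codes[i + j];
      if (b > 3) { ok = false; break; }
      accf += fwd(j, b);
      accr += rev(j, b);
    }
    if (ok) { sf[i] = accf; sr[i] = accr; }
    else    { sf[i] = NA_INTEGER; sr[i] = NA_INTEGER; }
  }
  return List::create(sf, sr);
}

// Early-exit variant: does any window on either strand reach `threshold`?

// [[Rcpp::export]]
bool scan_pwm_any(IntegerVector codes, IntegerMatrix fwd, IntegerMatrix rev,
                  int threshold) {
  const int n = codes.size();
  const int w = fwd.nrow();
  const int nwin = n - w + 1;
  for (int i = 0; i < nwin; ++i) {
    int accf = 0, accr = 0;
    bool ok = true;
    for (int j = 0; j < w; ++j) {
      const int b = codes[i + j];
      if (b > 3) { ok = false; break; }
      accf += fwd(j, b);
      accr += rev(j, b);
    }
    if (ok && (accf >= threshold || accr >= threshold)) return true;
  }
  return false;
}

// Batched variant over a list of integer-coded sequences; score matrices are
// flattened to position-major arrays for tight inner loops.

// [[Rcpp::export]]
LogicalVector scan_pwm_any_many(List codes_list, IntegerMatrix fwd,
                                IntegerMatrix rev, int threshold) {
  const int w = fwd.nrow();
  std::vector<int> f(4 * w), r(4 * w);
  for (int j = 0; j < w; ++j) {
    for (int b = 0; b < 4; ++b) {
      f[4 * j + b] = fwd(j, b);
      r[4 * j + b] = rev(j, b);
    }
  }
  const int nseq = codes_list.size();
  LogicalVector out(nseq);
  for (int s = 0; s < nseq; ++s) {
    IntegerVector codes(codes_list[s]);
    const int n = codes.size();
    const int nwin = n - w + 1;
    const int* cd = INTEGER(codes);
    bool hit = false;
    for (int i = 0; i < nwin && !hit; ++i) {
      int accf = 0, accr = 0;
      bool ok = true;
      const int* ci = cd + i;
      for (int j = 0; j < w; ++j) {
        const int b = ci[j];
        if (b > 3) { ok = false; break; }
        accf += f[4 * j + b];
        accr += r[4 * j + b];
      }
      hit = ok && (accf >= threshold || accr >= threshold);
    }
    out[s] = hit;
  }
  return out;
}
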