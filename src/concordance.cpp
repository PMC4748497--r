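#include <Rcpp.h>
using namespace Rcpp;

// Pairwise concordance counts for censored survival data.
//
// A pair is usable only if the member with strictly shorter follow-up had an
// event; pairs with tied follow-up times are never usable. A usable pair is
// concordant when the earlier event carries the higher predicted risk; tied
// predictions contribute 1/2.
// [[Rcpp::export]]
NumericVector concordance_counts(NumericVector time, LogicalVector event,
                                 NumericVector pred) {
  const int n = time.size();
  double concordant = 0.0, tied_pred = 0.0, usable = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      int a = i, b = j;
      if (time[j] < time[i]) { a = j; b = i; }
      else if (time[i] == time[j]) continue;
      if (!event[a]) continue;
      usable += 1.0;
      if (pred[a] > pred[b]) concordant += 1.0;
      else if (pred[a] == pred[b]) { concordant += 0.5; tied_pred += 1.0; }
    }
  }
  return NumericVector::create(_["concordant"] = concordant,
                               _["tied_pred"] = tied_pred,
                               _["usable"] = usable);
}
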