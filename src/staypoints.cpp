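// Stay-point scan over a chronologically ordered GPS trace (Li et al.-style
// time-based clustering): a run of fixes all within dist_m of the run's
// first fix, spanning at least time_min minutes, forms one stay point.
#include <Rcpp.h>
#include <cmath>

namespace {
const double kEarthRadiusKm = 6371.0;
double hav_m(double la1, double lo1, double la2, double lo2) {
  const double d2r = M_PI / 180.0;
  double dlat = (la2 - la1) * d2r, dlon = (lo2 - lo1) * d2r;
  double a = std::sin(dlat / 2) * std::sin(dlat / 2) +
             std::cos(la1 * d2r) * std::cos(la2 * d2r) *
                 std::sin(dlon / 2) * std::sin(dlon / 2);
  return 2.0 * kEarthRadiusKm * 1000.0 *
         std::atan2(std::sqrt(a), std::sqrt(1.0 - a));
}
}  // namespace

// Returns a per-fix stay-point id (0 = transit). t_min is the timestamp in
// minutes; fixes must be sorted by time.
// [[Rcpp::export]]
Rcpp::IntegerVector cpp_staypoint_scan(Rcpp::NumericVector lat,
                                       Rcpp::NumericVector lon,
                                       Rcpp::NumericVector t_min,
                                       double dist_m, double time_min) {
  const int n = lat.size();
  Rcpp::IntegerVector id(n, 0);
  int next_id = 1, i = 0;
  while (i < n) {
    int j = i + 1;
    while (j < n && hav_m(lat[i], lon[i], lat[j], lon[j]) <= dist_m) ++j;
    // fixes i..j-1 lie within dist_m of fix i
    if (j - i >= 2 && t_min[j - 1] - t_min[i] >= time_min) {
      for (int k = i; k < j; ++k) id[k] = next_id;
      ++next_id;
      i = j;
    } else {
      ++i;
    }
  }
  return id;
}
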