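#include <Rcpp.h>
using namespace Rcpp;

// Correlated random walk inside a circular well.
//
// Each frame moves exactly `step[i]` mm along a heading that evolves as a
// wrapped Gaussian (SD `turn_sd` rad). When a step would leave the well the
// heading is redrawn uniformly (a "turn at the wall"); after a bounded
// number of rejected draws the fish heads straight for the centre. Every
// accepted displacement therefore has length step[i] exactly, so summed
// path length equals summed speed * dt bit-for-bit.
//
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
NumericMatrix track_walk(NumericVector step, double radius, double turn_sd,
                         double x0, double y0) {
  int n = step.size();
  NumericMatrix out(n + 1, 2);
  RNGScope scope;
  double x = x0, y = y0;
  if (std::sqrt(x * x + y * y) > radius)
    stop("start position outside the well");
  out(0, 0) = x;
  out(0, 1) = y;
  double heading = unif_rand() * M_2PI;
  for (int i = 0; i < n; ++i) {
    double s = step[i];
    if (s > 2.0 * radius)
      stop("per-frame step exceeds the well diameter; lower the speed or frame interval");
    heading += norm_rand() * turn_sd;
    double nx = x + s * std::cos(heading);
    double ny = y + s * std::sin(heading);
    int tries = 0;
    while (nx * nx + ny * ny > radius * radius && tries < 50) {
      heading = unif_rand() * M_2PI;
      nx = x + s * std::cos(heading);
      ny = y + s * std::sin(heading);
      ++tries;
    }
    if (nx * nx + ny * ny > radius * radius) {
      // Aim at the centre; from any interior point a chord through the
      // centre has length >= radius >= s whenever s <= radius.
      heading = std::atan2(-y, -x);
      nx = x + s * std::cos(heading);
      ny = y + s * std::sin(heading);
      if (nx * nx + ny * ny > radius * radius)
        stop("step too long for the well geometry");
    }
    x = nx;
    y = ny;
    out(i + 1, 0) = x;
    out(i + 1, 1) = y;
  }
  return out;
}
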