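#include <Rcpp.h>
using namespace Rcpp;

// First-passage simulation of a Wiener process with two absorbing
// boundaries at 0 and a, start point a/2, drift v, diffusion scale s.
// Increments over dt are exact in distribution (constant coefficients),
// so the only discretisation error is missed within-step boundary
// crossings; with bridge = true the crossing probability of each
// boundary over the step is evaluated from the Brownian-bridge law and
// resolved by an auxiliary uniform draw, removing the leading-order
// bias of naive Euler sampling.
//
// Returns a 2-column matrix: decision time (s), upper-boundary flag.
// [[Rcpp::export(name = ".wiener_fpt")]]
NumericMatrix wiener_fpt(int n_trials, double v, double a, double s,
                         double dt, bool bridge, double max_time) {
  NumericMatrix out(n_trials, 2);
  const double sd_step = s * std::sqrt(dt);
  const double mu_step = v * dt;
  const double s2dt = s * s * dt;
  const double start = a / 2.0;

  for (int i = 0; i < n_trials; ++i) {
    double x = start;
    double t = 0.0;
    int hit = -1; // 0 lower, 1 upper
    while (t < max_time) {
      double x1 = x + mu_step + norm_rand() * sd_step;
      t += dt;
      if (x1 >= a) { hit = 1; break; }
      if (x1 <= 0.0) { hit = 0; break; }
      if (bridge) {
        // Brownian-bridge probability that the within-step path touched
        // a boundary although both endpoints are interior.
        double p_up = std::exp(-2.0 * (a - x) * (a - x1) / s2dt);
        double p_dn = std::exp(-2.0 * x * x1 / s2dt);
        double u = unif_rand();
        if (u < p_up) { hit = 1; break; }
        if (u < p_up + p_dn) { hit = 0; break; }
      }
      x = x1;
    }
    if (hit < 0) stop("first-passage time exceeded max_time; check parameters");
    out(i, 0) = t;
    out(i, 1) = hit;
  }
  return out;
}
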