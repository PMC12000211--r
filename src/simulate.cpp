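#include <Rcpp.h>
using namespace Rcpp;

// Euler-Maruyama simulation of the 2-D accumulation process with
// projection stopping rules. One entry per trial in the parameter
// vectors; drift vectors are pre-perturbed (across-trial variability is
// resampled in R before the call). Uses R's RNG so seeding is controlled
// by set.seed() on the R side.
//
// Stopping: the first step at which the component of the state along
// u_A or u_B reaches theta triggers the corresponding choice; a same-step
// double crossing is broken by the larger projection, exact ties by a
// fair coin. Trials that never cross before t_max are flagged censored.
//
// choice: 0 = A, 1 = B, NA = censored. rt is the decision time on the
// discrete grid (non-decision time is added in R).
// [[Rcpp::export]]
List simulate_core(NumericVector mu_x, NumericVector mu_y,
                   NumericVector theta, NumericVector gamma,
                   NumericVector x0, NumericVector y0,
                   double dt, double t_max, double sigma,
                   bool keep_trace) {
  const int n = mu_x.size();
  NumericVector rt(n), fx(n), fy(n);
  IntegerVector choice(n), nsteps(n);
  LogicalVector censored(n);
  List traces = keep_trace ? List(n) : List(0);

  const double sdt = sigma * std::sqrt(dt);
  const long max_steps = (long)std::ceil(t_max / dt);
  RNGScope scope;

  for (int i = 0; i < n; i++) {
    const double th = theta[i];
    const double ca = std::cos(gamma[i]), sa = std::sin(gamma[i]);
    const bool oneD = std::fabs(sa) < 1e-12;  // opposed options: y never enters
    const double mxdt = mu_x[i] * dt, mydt = mu_y[i] * dt;
    double x = x0[i], y = y0[i];
    std::vector<double> tr;
    if (keep_trace) tr.reserve(256);

    int ch = NA_INTEGER;
    long step = 0;
    double pA = x, pB = x * ca + y * sa;
    bool done = (pA >= th) || (pB >= th);
    if (done) {  // start point already beyond a boundary
      if (pA >= th && pB >= th) {
        ch = (pA > pB) ? 0 : (pB > pA ? 1 : (unif_rand() < 0.5 ? 0 : 1));
      } else ch = (pA >= th) ? 0 : 1;
    }
    while (!done && step < max_steps) {
      const double ex = mxdt + sdt * norm_rand();
      const double ey = oneD ? 0.0 : (mydt + sdt * norm_rand());
      x += ex;
      y += ey;
      step++;
      if (keep_trace) tr.push_back(ex * (1.0 - ca) - ey * sa);  // balance increment
      pA = x;
      pB = x * ca + y * sa;
      if (pA >= th || pB >= th) {
        if (pA >= th && pB >= th) {
          ch = (pA > pB) ? 0 : (pB > pA ? 1 : (unif_rand() < 0.5 ? 0 : 1));
        } else ch = (pA >= th) ? 0 : 1;
        done = true;
      }
    }
    choice[i] = ch;
    censored[i] = !done;
    rt[i] = step * dt;
    nsteps[i] = (int)step;
    fx[i] = x;
    fy[i] = y;
    if (keep_trace) traces[i] = NumericVector(tr.begin(), tr.end());
  }

  List out = List::create(
    _["choice"] = choice, _["rt"] = rt, _["n_steps"] = nsteps,
    _["censored"] = censored, _["x"] = fx, _["y"] = fy);
  if (keep_trace) out["trace"] = traces;
  return out;
}
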