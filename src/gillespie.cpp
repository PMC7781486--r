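#include <Rcpp.h>
using namespace Rcpp;

// Direct-method stochastic simulation of a mass-action reaction network.
//
// Propensities are mass-action with combinatorial falling factorials for
// stoichiometries > 1. Two special per-reaction kinds encode the
// double-monomer requirement of the first Cre excision (two Cre monomers
// must be present, one is consumed, the deterministic rate stays k*Z00*C):
//   kind 1 ("linear_guard"): plain mass-action propensity, zeroed unless the
//     guard species count is >= guard_min;
//   kind 2 ("combinatorial"): propensity additionally multiplied by
//     (n_guard - 1) / 2, the pair-counting alternative.
//
// Uses R's RNG (unif_rand) so trajectories are reproducible via set.seed().
//
// dna_idx marks the platform-address species (0-based); the state at the
// last event where their total was positive is returned alongside the final
// state, so callers can take the surviving-fraction limit when the DNA pool
// goes extinct.

static double propensity(const IntegerMatrix& reactants, int r, int kind,
                         int guard_species, int guard_min,
                         const NumericVector& rates, const std::vector<double>& x,
                         int nspecies) {
  double a = rates[r];
  if (a <= 0.0) return 0.0;
  for (int j = 0; j < nspecies; ++j) {
    int s = reactants(r, j);
    if (s == 0) continue;
    double n = x[j];
    if (s == 1) {
      a *= n;
    } else {
      // falling factorial / s! (stoichiometry > 1, combinatorial counting)
      double f = 1.0;
      for (int q = 0; q < s; ++q) f *= (n - q) / (q + 1.0);
      a *= (f > 0.0) ? f : 0.0;
    }
    if (a <= 0.0) return 0.0;
  }
  if (kind != 0 && guard_species >= 0) {
    double g = x[guard_species];
    if (g < guard_min) return 0.0;
    if (kind == 2) a *= (g - 1.0) / 2.0;  // pair-counting alternative
  }
  return a;
}

// [[Rcpp::export]]
List gillespie_cpp(IntegerMatrix reactants, IntegerMatrix products,
                   NumericVector rates, IntegerVector kinds,
                   IntegerVector guard_species, IntegerVector guard_min,
                   IntegerVector init, int max_reactions, double max_time,
                   IntegerVector dna_idx, bool record) {
  const int nr = reactants.nrow();
  const int ns = reactants.ncol();
  std::vector<double> x(ns);
  for (int j = 0; j < ns; ++j) {
    if (init[j] < 0) stop("initial counts must be non-negative");
    x[j] = init[j];
  }

  RNGScope scope;

  std::vector<double> times;
  std::vector<int> which_rx;
  std::vector<double> states;   // row-major ns per event
  if (record) {
    times.reserve(max_reactions + 1);
    states.reserve((size_t)(max_reactions + 1) * ns);
  }

  double t = 0.0;
  int events = 0;
  std::string reason = "max_reactions";

  std::vector<double> last_pos(x);
  double last_pos_t = 0.0;
  auto dna_total = [&](const std::vector<double>& v) {
    double s = 0.0;
    for (int k = 0; k < dna_idx.size(); ++k) s += v[dna_idx[k]];
    return s;
  };
  bool have_pos = dna_total(x) > 0.0;

  std::vector<double> a(nr);
  while (events < max_reactions) {
    double a0 = 0.0;
    for (int r = 0; r < nr; ++r) {
      a[r] = propensity(reactants, r, kinds[r], guard_species[r], guard_min[r],
                        rates, x, ns);
      a0 += a[r];
    }
    if (a0 <= 0.0) { reason = "exhausted"; break; }

    double u1 = unif_rand();
    if (u1 <= 0.0) u1 = 1e-300;
    double tau = -std::log(u1) / a0;
    if (R_finite(max_time) && t + tau > max_time) { t = max_time; reason = "max_time"; break; }
    t += tau;

    double u2 = unif_rand() * a0;
    int r = 0;
    double cum = a[0];
    while (cum < u2 && r < nr - 1) { cum += a[++r]; }

    for (int j = 0; j < ns; ++j) {
      x[j] += products(r, j) - reactants(r, j);
      if (x[j] < 0) stop("negative molecule count: propensity/guard inconsistency");
    }
    ++events;

    if (dna_total(x) > 0.0) {
      last_pos = x;
      last_pos_t = t;
      have_pos = true;
    }
    if (record) {
      times.push_back(t);
      which_rx.push_back(r + 1);
      for (int j = 0; j < ns; ++j) states.push_back(x[j]);
    }
  }

  NumericVector final_state(ns), last_nonempty(ns);
  for (int j = 0; j < ns; ++j) {
    final_state[j] = x[j];
    last_nonempty[j] = have_pos ? last_pos[j] : NA_REAL;
  }

  List out = List::create(
    _["final_state"] = final_state,
    _["final_time"] = t,
    _["n_events"] = events,
    _["stopped"] = reason,
    _["last_nonempty_state"] = last_nonempty,
    _["last_nonempty_time"] = have_pos ? last_pos_t : NA_REAL
  );
  if (record) {
    NumericMatrix st(events, ns);
    for (int i = 0; i < events; ++i)
      for (int j = 0; j < ns; ++j) st(i, j) = states[(size_t)i * ns + j];
    out["times"] = NumericVector(times.begin(), times.end());
    out["reaction"] = IntegerVector(which_rx.begin(), which_rx.end());
    out["states"] = st;
  }
  return out;
}
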