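// Bound-constrained trust-region nonlinear least squares with a
// two-dimensional subspace subproblem, specialised to the multi-component
// magnitude inversion-recovery signal model, plus a generic R-callback
// interface for arbitrary residual functions.
//
// Parameterisation: the solver first maps parameters to unit-box
// coordinates z = (x - lower) / (upper - lower), so the trust region is
// well conditioned across M0 (signal units) and T1 (ms) coordinates, and
// then applies Coleman-Li interior-reflective scaling: at each iterate a
// diagonal matrix D = diag(sqrt(v)) built from the distance to the bound
// faced by the negative gradient rescales the model, and steps that would
// cross a bound are truncated to a strictly interior point with a
// reflected continuation considered as an alternative.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

namespace {

struct Ctrl {
  int max_iter;
  double gtol, xtol, delta0, shrink, grow, accept_lo, accept_hi;
};

Ctrl parse_ctrl(const List& ctrl) {
  Ctrl c;
  c.max_iter = as<int>(ctrl["max_iterations"]);
  c.gtol = as<double>(ctrl["gradient_tolerance"]);
  c.xtol = as<double>(ctrl["step_tolerance"]);
  c.delta0 = as<double>(ctrl["initial_radius"]);
  c.shrink = as<double>(ctrl["radius_shrink"]);
  c.grow = as<double>(ctrl["radius_grow"]);
  c.accept_lo = as<double>(ctrl["accept_threshold_low"]);
  c.accept_hi = as<double>(ctrl["accept_threshold_high"]);
  return c;
}

// Residual evaluator interface: fills r(x) and J = dr/dx.
struct Evaluator {
  virtual bool eval(const arma::vec& x, arma::vec& r, arma::mat& J) = 0;
  virtual ~Evaluator() {}
};

// r_i = y_i - sum_j m0_j |1 - 2 exp(-ti_i / t1_j)|, x = (m0_1..n, t1_1..n).
// At the kink (argument exactly zero) the subgradient sign(0) = 0 is used.
struct IrEvaluator : public Evaluator {
  arma::vec ti, y;
  int n;
  IrEvaluator(const arma::vec& ti_, const arma::vec& y_, int n_)
    : ti(ti_), y(y_), n(n_) {}
  bool eval(const arma::vec& x, arma::vec& r, arma::mat& J) {
    const arma::uword m = ti.n_elem;
    r = y;
    J.zeros(m, 2 * n);
    for (int j = 0; j < n; ++j) {
      const double m0 = x(j), t1 = x(n + j);
      if (!(t1 > 0)) return false;
      for (arma::uword i = 0; i < m; ++i) {
        const double e = std::exp(-ti(i) / t1);
        const double k = 1.0 - 2.0 * e;
        const double a = std::fabs(k);
        const double sg = (k > 0) - (k < 0);
        r(i) -= m0 * a;
        J(i, j) = -a;
        // d model / d t1 = m0 * sign(k) * (-2 e ti / t1^2); residual flips sign
        J(i, n + j) = m0 * sg * 2.0 * e * ti(i) / (t1 * t1);
      }
    }
    return r.is_finite() && J.is_finite();
  }
};

struct FnEvaluator : public Evaluator {
  Function rf, jf;
  FnEvaluator(Function rf_, Function jf_) : rf(rf_), jf(jf_) {}
  bool eval(const arma::vec& x, arma::vec& r, arma::mat& J) {
    r = as<arma::vec>(rf(NumericVector(x.begin(), x.end())));
    J = as<arma::mat>(jf(NumericVector(x.begin(), x.end())));
    return r.is_finite() && J.is_finite();
  }
};

double model_value(const arma::vec& g, const arma::mat& B, const arma::vec& s) {
  return arma::dot(g, s) + 0.5 * arma::dot(s, B * s);
}

// Exact trust-region subproblem in the reduced space (dim <= 2):
// minimize gr' w + 0.5 w' Br w subject to ||w|| <= radius.
arma::vec small_trs(const arma::vec& gr, const arma::mat& Br, double radius) {
  const arma::uword d = gr.n_elem;
  arma::vec eval;
  arma::mat evec;
  if (!arma::eig_sym(eval, evec, arma::symmatu(Br)))
    return arma::zeros<arma::vec>(d);
  arma::vec gh = evec.t() * gr;
  const double lam_min = eval.min();

  if (lam_min > 0) {
    arma::vec w = -(gh / eval);
    if (arma::norm(w) <= radius) return evec * w;
  }

  const double mu_lo = std::max(0.0, -lam_min);
  auto w_of = [&](double mu) {
    arma::vec w(d);
    for (arma::uword i = 0; i < d; ++i) {
      const double den = eval(i) + mu;
      w(i) = (std::fabs(den) > 1e-300) ? -gh(i) / den : 0.0;
    }
    return w;
  };

  // Hard case: the limit solution at mu_lo is already inside the sphere.
  const double bump = 1e-12 * std::max(1.0, std::fabs(lam_min)) + 1e-300;
  arma::vec w_lim = w_of(mu_lo + bump);
  if (arma::norm(w_lim) < radius && mu_lo > 0) {
    arma::vec w(d, arma::fill::zeros);
    for (arma::uword i = 0; i < d; ++i)
      if (eval(i) + mu_lo > bump) w(i) = -gh(i) / (eval(i) + mu_lo);
    double rem = radius * radius - arma::dot(w, w);
    if (rem > 0) {
      // add along an eigendirection of the smallest eigenvalue
      for (arma::uword i = 0; i < d; ++i)
        if (std::fabs(eval(i) - lam_min) <= 1e-10 * std::max(1.0, std::fabs(lam_min))) {
          w(i) += std::sqrt(rem);
          break;
        }
    }
    return evec * w;
  }

  // Safeguarded bisection on mu for ||w(mu)|| = radius.
  double lo = mu_lo + bump;
  double hi = mu_lo + arma::norm(gh) / std::max(radius, 1e-300) + 1.0;
  while (arma::norm(w_of(hi)) > radius) hi = 2.0 * hi + 1.0;
  for (int it = 0; it < 200; ++it) {
    const double mid = 0.5 * (lo + hi);
    if (arma::norm(w_of(mid)) > radius) lo = mid; else hi = mid;
    if (hi - lo <= 1e-14 * std::max(1.0, hi)) break;
  }
  return evec * w_of(hi);
}

// Step minimizing the quadratic model over span{-g, v} within the region,
// where v is the (Gauss-)Newton direction B v = -g; falls back to the
// one-dimensional gradient subspace when B is singular.
arma::vec trs_2d_step(const arma::vec& g, const arma::mat& B, double radius) {
  const arma::uword p = g.n_elem;
  const double gn = arma::norm(g);
  if (!(gn > 0)) return arma::zeros<arma::vec>(p);

  arma::mat Q(p, 2);
  arma::uword dim = 1;
  Q.col(0) = -g / gn;
  arma::vec v;
  const bool ok = arma::solve(v, arma::symmatu(B), -g,
                              arma::solve_opts::no_approx);
  if (ok && v.is_finite()) {
    arma::vec q2 = v - arma::dot(Q.col(0), v) * Q.col(0);
    const double q2n = arma::norm(q2);
    if (q2n > 1e-10 * std::max(arma::norm(v), 1.0)) {
      Q.col(1) = q2 / q2n;
      dim = 2;
    }
  }
  const arma::mat Qd = Q.cols(0, dim - 1);
  const arma::vec gr = Qd.t() * g;
  const arma::mat Br = Qd.t() * B * Qd;
  return Qd * small_trs(gr, Br, radius);
}

// Largest alpha >= 0 with z + alpha s inside [0, 1]^p; flags coords that hit.
double step_to_box(const arma::vec& z, const arma::vec& s,
                   std::vector<bool>& hit) {
  double alpha = arma::datum::inf;
  hit.assign(z.n_elem, false);
  for (arma::uword i = 0; i < z.n_elem; ++i) {
    double a = arma::datum::inf;
    if (s(i) > 0) a = (1.0 - z(i)) / s(i);
    else if (s(i) < 0) a = -z(i) / s(i);
    if (a < alpha) alpha = a;
  }
  if (!std::isfinite(alpha)) return alpha;
  for (arma::uword i = 0; i < z.n_elem; ++i) {
    if (s(i) > 0 && (1.0 - z(i)) / s(i) <= alpha * (1 + 1e-12)) hit[i] = true;
    else if (s(i) < 0 && -z(i) / s(i) <= alpha * (1 + 1e-12)) hit[i] = true;
  }
  return alpha;
}

const double kTheta = 0.995;  // strict-interior step-back fraction

// Choose the trial step in Coleman-Li hat space: candidates are the
// bound-truncated 2D-subspace step, its reflection off the first bound
// hit, and the bound-truncated Cauchy step; the candidate of least model
// value wins, so the step is never worse (in model value) than the
// feasible truncated Cauchy step. dcl maps hat steps to z steps.
arma::vec select_step(const arma::vec& z, const arma::vec& g_h,
                      const arma::mat& B_h, const arma::vec& dcl,
                      double radius) {
  std::vector<bool> hit;
  arma::vec best;
  double best_m = arma::datum::inf;
  auto consider = [&](const arma::vec& sh) {
    if (!sh.is_finite()) return;
    const double m = model_value(g_h, B_h, sh);
    if (std::isfinite(m) && m < best_m) { best_m = m; best = sh; }
  };
  auto box_alpha = [&](const arma::vec& sh, std::vector<bool>& h) {
    return step_to_box(z, dcl % sh, h);
  };

  const arma::vec s2d = trs_2d_step(g_h, B_h, radius);
  const double a2d = box_alpha(s2d, hit);
  consider(std::min(1.0, kTheta * a2d) * s2d);

  // reflected continuation when the 2D step is cut by a bound
  if (a2d < 1.0 && std::isfinite(a2d)) {
    const arma::vec base = (kTheta * a2d) * s2d;
    arma::vec rdir = s2d;
    for (arma::uword i = 0; i < rdir.n_elem; ++i)
      if (hit[i]) rdir(i) = -rdir(i);
    std::vector<bool> hit2;
    const double t_box = kTheta * step_to_box(z + dcl % base, dcl % rdir, hit2);
    // stay within the trust region: ||base + t rdir|| <= radius
    const double rr = arma::dot(rdir, rdir);
    double t_tr = arma::datum::inf;
    if (rr > 0) {
      const double br = arma::dot(base, rdir);
      const double disc = br * br - rr * (arma::dot(base, base) - radius * radius);
      t_tr = disc >= 0 ? (-br + std::sqrt(disc)) / rr : 0.0;
    }
    const double t_max = std::min(t_box, t_tr);
    if (std::isfinite(t_max) && t_max > 0) {
      const double qa = arma::dot(rdir, B_h * rdir);
      const double qb = arma::dot(g_h, rdir) + arma::dot(base, B_h * rdir);
      const double t = (qa > 0) ? std::min(std::max(-qb / qa, 0.0), t_max)
                                : (qb < 0 ? t_max : 0.0);
      consider(base + t * rdir);
    }
  }

  // truncated Cauchy step along the scaled negative gradient
  const double gn2 = arma::dot(g_h, g_h);
  if (gn2 > 0) {
    const double gBg = arma::dot(g_h, B_h * g_h);
    const double t_tr = radius / std::sqrt(gn2);
    const double t = (gBg > 0) ? std::min(gn2 / gBg, t_tr) : t_tr;
    const arma::vec sc = -t * g_h;
    const double ac = box_alpha(sc, hit);
    consider(std::min(1.0, kTheta * ac) * sc);
  }

  if (!best.is_finite() || best.n_elem != z.n_elem)
    best = arma::zeros<arma::vec>(z.n_elem);
  return best;
}

List trf_core(Evaluator& ev, const arma::vec& x0, const arma::vec& lower,
              const arma::vec& upper, const Ctrl& c) {
  const arma::uword p = x0.n_elem;
  if (lower.n_elem != p || upper.n_elem != p)
    stop("bounds must match the parameter dimension");
  if (arma::any(upper <= lower))
    stop("lower bounds must be strictly below upper bounds");

  const arma::vec d = upper - lower;
  arma::vec z = (x0 - lower) / d;
  z = arma::clamp(z, 1e-10, 1.0 - 1e-10);  // project strictly inward

  arma::vec r;
  arma::mat J;
  std::string status = "maxiter";
  bool converged = false;

  auto objective_at = [&](const arma::vec& zz, arma::vec& rr, arma::mat& JJ,
                          bool& ok) {
    ok = ev.eval(lower + d % zz, rr, JJ);
    return ok ? arma::dot(rr, rr) : arma::datum::inf;
  };

  bool ok = false;
  double f = objective_at(z, r, J, ok);
  if (!ok) {
    return List::create(_["x"] = NumericVector(p),
                        _["objective"] = NA_REAL,
                        _["iterations"] = 0, _["converged"] = false,
                        _["status"] = "objective not finite at starting point",
                        _["trace"] = NumericVector::create());
  }

  arma::mat Jd = J * arma::diagmat(d);
  arma::vec g = 2.0 * (Jd.t() * r);
  arma::mat B = 2.0 * (Jd.t() * Jd);

  double radius = c.delta0;
  int iter = 0;
  std::vector<double> trace;
  trace.push_back(f);

  while (true) {
    // Coleman-Li distances to the bound faced by the negative gradient,
    // and the first-order optimality measure they induce
    arma::vec v(p), dv(p);
    double crit = 0.0;
    for (arma::uword i = 0; i < p; ++i) {
      if (g(i) < 0) { v(i) = 1.0 - z(i); dv(i) = -1.0; }
      else          { v(i) = z(i);       dv(i) = 1.0; }
      crit = std::max(crit, std::fabs(v(i) * g(i)));
    }
    if (crit <= c.gtol * std::max(1.0, f)) {
      converged = true;
      status = "gradient tolerance";
      break;
    }
    if (iter >= c.max_iter) { status = "maxiter"; break; }
    ++iter;

    if (!g.is_finite() || !B.is_finite()) {
      status = "non-finite gradient or Hessian";
      break;
    }

    // hat-space model: g_h = D g, B_h = D B D + diag(g * dv), D = diag(sqrt(v))
    const arma::vec dcl = arma::sqrt(v);
    const arma::vec g_h = dcl % g;
    arma::mat B_h = B;
    B_h.each_col() %= dcl;
    B_h.each_row() %= dcl.t();
    B_h.diag() += g % dv;

    const arma::vec sh = select_step(z, g_h, B_h, dcl, radius);
    const double pred = -model_value(g_h, B_h, sh);
    const double snorm = arma::norm(sh);

    if (!(pred > 0) || snorm == 0) {
      radius *= c.shrink;
      if (radius < 1e-16) { converged = true; status = "radius collapsed"; break; }
      continue;
    }

    arma::vec r_new;
    arma::mat J_new;
    bool ok_new = false;
    const arma::vec z_new = z + dcl % sh;
    const double f_new = objective_at(z_new, r_new, J_new, ok_new);
    const double rho = ok_new ? (f - f_new) / pred : -arma::datum::inf;

    if (!ok_new || !(f_new < f)) {
      // no actual reduction: reject and shrink towards the attempted step
      radius = c.shrink * std::min(radius, snorm);
      if (radius < 1e-16) { converged = true; status = "radius collapsed"; break; }
      continue;
    }

    // accepted: poor model agreement shrinks the region, very good
    // agreement on a near-boundary step grows it
    if (rho < c.accept_lo) radius = c.shrink * std::min(radius, snorm);
    else if (rho > c.accept_hi && snorm >= 0.8 * radius) radius *= c.grow;

    z = z_new;
    r = r_new;
    f = f_new;
    Jd = J_new * arma::diagmat(d);
    g = 2.0 * (Jd.t() * r);
    B = 2.0 * (Jd.t() * Jd);
    trace.push_back(f);

    if (snorm <= c.xtol * (c.xtol + arma::norm(z))) {
      converged = true;
      status = "step tolerance";
      break;
    }
    if (radius < 1e-16) { converged = true; status = "radius collapsed"; break; }
  }

  const arma::vec x = lower + d % z;
  return List::create(_["x"] = NumericVector(x.begin(), x.end()),
                      _["objective"] = f,
                      _["iterations"] = iter,
                      _["converged"] = converged,
                      _["status"] = status,
                      _["trace"] = NumericVector(trace.begin(), trace.end()));
}

}  // namespace

// [[Rcpp::export]]
List trf_solve_ir_cpp(const arma::vec& ti, const arma::vec& y,
                      int n_components, const arma::vec& x0,
                      const arma::vec& lower, const arma::vec& upper,
                      const List& control) {
  IrEvaluator ev(ti, y, n_components);
  return trf_core(ev, x0, lower, upper, parse_ctrl(control));
}

// [[Rcpp::export]]
List trf_multistart_ir_cpp(const arma::vec& ti, const arma::vec& y,
                           int n_components, const arma::mat& starts,
                           const arma::vec& lower, const arma::vec& upper,
                           const List& control) {
  IrEvaluator ev(ti, y, n_components);
  const Ctrl c = parse_ctrl(control);
  const int ns = starts.n_rows;
  NumericVector objectives(ns);
  IntegerVector iterations(ns);
  LogicalVector converged(ns);
  CharacterVector statuses(ns);
  arma::vec best_x;
  double best_f = arma::datum::inf;
  int best_i = -1;
  for (int i = 0; i < ns; ++i) {
    List fit = trf_core(ev, starts.row(i).t(), lower, upper, c);
    const double fi = fit["objective"];
    objectives[i] = fi;
    iterations[i] = as<int>(fit["iterations"]);
    converged[i] = as<bool>(fit["converged"]);
    statuses[i] = as<std::string>(fit["status"]);
    if (std::isfinite(fi) && fi < best_f) {
      best_f = fi;
      best_i = i;
      best_x = as<arma::vec>(fit["x"]);
    }
  }
  return List::create(_["best_index"] = best_i + 1,
                      _["best_x"] = best_i >= 0
                        ? NumericVector(best_x.begin(), best_x.end())
                        : NumericVector(0),
                      _["best_objective"] = best_f,
                      _["objectives"] = objectives,
                      _["iterations"] = iterations,
                      _["converged"] = converged,
                      _["statuses"] = statuses);
}

// [[Rcpp::export]]
List trf_solve_fn_cpp(Function resid_fn, Function jac_fn, const arma::vec& x0,
                      const arma::vec& lower, const arma::vec& upper,
                      const List& control) {
  FnEvaluator ev(resid_fn, jac_fn);
  return trf_core(ev, x0, lower, upper, parse_ctrl(control));
}

// [[Rcpp::export]]
NumericVector trs_2d_step_cpp(const arma::vec& gradient,
                              const arma::mat& hessian, double radius) {
  const arma::vec s = trs_2d_step(gradient, hessian, radius);
  return NumericVector(s.begin(), s.end());
}
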