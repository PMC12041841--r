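// Fast path for the penalized two-part model: closed-form estimators,
// information-criterion penalty selection (continuous search or grid scan),
// and the permutation loop.  The R level carries the documented reference
// implementations of the same quantities; tests assert both paths agree.
#include <RcppArmadillo.h>
#include <map>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using namespace arma;

static const double LOG2PI = 1.837877066409345483560659472811;

// Everything about one model (alternative or null) that does not depend on
// the penalty: centered masked residuals, entry-wise numerator/denominator,
// Bernoulli log-likelihood at the closed-form estimates, support patterns.
struct ModelCtx {
  mat Zc;                        // centered residuals, 0 at absences
  mat B;                         // unpenalized covariance estimate
  vec w;                         // 1 / diag(denominator)
  double bernll;                 // Bernoulli part of the log-likelihood
  double icconst;                // log(n) + 0.5 * log(p)
  int n, p;
  const std::vector<uvec>* vidx;
  const std::vector<uvec>* midx;
  const uvec* nik;
};

static ModelCtx build_ctx(const mat& Z, const mat& Y, const uvec& glab,
                          int K, bool null_model,
                          const std::vector<uvec>& vidx,
                          const std::vector<uvec>& midx,
                          const uvec& nik)
{
  ModelCtx c;
  c.n = Z.n_rows; c.p = Z.n_cols;
  c.vidx = &vidx; c.midx = &midx; c.nik = &nik;
  const int G = null_model ? 1 : K;

  // observed-components-only means, per group (alternative) or pooled (null)
  mat mu(G, c.p, fill::zeros), cnt(G, c.p, fill::zeros);
  for (int i = 0; i < c.n; ++i) {
    const int g = null_model ? 0 : (int)glab(i);
    for (int j = 0; j < c.p; ++j)
      if (Y(i, j) > 0.5) { mu(g, j) += Z(i, j); cnt(g, j) += 1.0; }
  }
  mu /= cnt; // caller guarantees cnt > 0 everywhere

  c.Zc.set_size(c.n, c.p);
  for (int i = 0; i < c.n; ++i) {
    const int g = null_model ? 0 : (int)glab(i);
    for (int j = 0; j < c.p; ++j)
      c.Zc(i, j) = (Y(i, j) > 0.5) ? (Z(i, j) - mu(g, j)) : 0.0;
  }

  const mat N  = c.Zc.t() * c.Zc;  // Hadamard-masked cross products
  const mat Dm = Y.t() * Y;        // pairwise co-observation counts
  c.B = N / Dm;                    // entry-wise; filter guarantees Dm > 0
  c.w = 1.0 / Dm.diag();

  // Bernoulli part: log pi_hat(s) = log(count_{g,s}/n_g) - log C(p, s)
  vec ngroup(G, fill::zeros);
  mat scnt(G, c.p + 1, fill::zeros);
  for (int i = 0; i < c.n; ++i) {
    const int g = null_model ? 0 : (int)glab(i);
    ngroup(g) += 1.0;
    scnt(g, nik(i)) += 1.0;
  }
  c.bernll = 0.0;
  for (int i = 0; i < c.n; ++i) {
    const int g = null_model ? 0 : (int)glab(i);
    c.bernll += std::log(scnt(g, nik(i)) / ngroup(g))
              - R::lchoose((double)c.p, (double)nik(i));
  }
  c.icconst = std::log((double)c.n) + 0.5 * std::log((double)c.p);
  return c;
}

struct CandEval {
  bool feasible;
  double ll, trsum, ic;
};

// Feasibility: Cholesky success plus a 1-norm condition bound
// 1/(||S||_1 ||S^{-1}||_1) > 1e-10, a lower bound for min-eig/max-eig.
// Per-row determinants/quadratics/traces use whichever of the observed set
// V or its complement M is smaller: a direct Cholesky of Sigma_VV, or the
// Schur identities Sigma_VV^{-1} = P_VV - P_VM P_MM^{-1} P_MV and
// log|Sigma_VV| = log|Sigma| + log|P_MM| with P = Sigma^{-1}.
static CandEval eval_lambda(const ModelCtx& c, double lam, bool feas_only)
{
  CandEval out;
  out.feasible = false;
  out.ll = out.trsum = out.ic = datum::nan;

  mat S = c.B;
  S.diag() += lam * c.w;
  mat R;
  if (!chol(R, S)) return out;
  if (feas_only) { out.feasible = true; return out; }  // boundary bracketing
  const mat Ri = inv(trimatu(R));
  const mat P  = Ri * Ri.t();
  if (1.0 / (norm(S, 1) * norm(P, 1)) <= 1e-10) return out;
  out.feasible = true;

  const double logdetS = 2.0 * accu(log(R.diag()));
  const vec pdiag = P.diag();
  const mat U = P * c.Zc.t();            // P x_i for every row at once
  double gll = 0.0, trs = 0.0;
  for (int i = 0; i < c.n; ++i) {
    const int v = (int)(*c.nik)(i);
    if (v == 0) continue;                // all-absent row: Bernoulli only
    const uvec& vi = (*c.vidx)[i];
    const uvec& mi = (*c.midx)[i];
    double logdet, quad, tri;
    if (v == c.p) {
      vec u = solve(trimatl(R.t()), c.Zc.row(i).t());
      logdet = logdetS;
      quad = dot(u, u);
      tri = accu(square(Ri));
    } else if (2 * v <= c.p) {
      mat Sv = S(vi, vi);
      mat Rv;
      if (!chol(Rv, Sv)) { out.feasible = false; return out; }
      vec x = c.Zc.row(i).t();
      vec u = solve(trimatl(Rv.t()), vec(x(vi)));
      logdet = 2.0 * accu(log(Rv.diag()));
      quad = dot(u, u);
      tri = accu(square(mat(inv(trimatu(Rv)))));
    } else {
      mat Pmm = P(mi, mi);
      mat Rm;
      if (!chol(Rm, Pmm)) { out.feasible = false; return out; }
      vec u = U.col(i);                  // rows of Zc are zero on the absent set
      vec b = solve(trimatl(Rm.t()), vec(u(mi)));
      logdet = logdetS + 2.0 * accu(log(Rm.diag()));
      quad = dot(c.Zc.row(i).t(), u) - dot(b, b);
      mat T = solve(trimatl(Rm.t()), mat(P(mi, vi)));
      tri = accu(vec(pdiag(vi))) - accu(square(T));
    }
    gll += -0.5 * ((double)v * LOG2PI + logdet + quad);
    trs += tri;
  }
  out.ll = c.bernll + gll;
  out.trsum = trs;
  out.ic = -2.0 * out.ll + c.icconst * trs;
  return out;
}

struct SelOut {
  bool ok;
  double lambda, ll, trsum, ic;
  vec grid_ic;       // grid mode diagnostics
  uvec grid_feas;
};

// Grid scan: IC argmin over feasible candidates, ties to the smaller value.
static SelOut select_grid(const ModelCtx& c, const vec& grid)
{
  SelOut s;
  s.ok = false;
  const int nc = grid.n_elem;
  s.grid_ic.set_size(nc); s.grid_feas.zeros(nc);
  double best = datum::inf;
  for (int k = 0; k < nc; ++k) {
    CandEval e = eval_lambda(c, grid(k), false);
    s.grid_ic(k) = e.ic;
    s.grid_feas(k) = e.feasible ? 1 : 0;
    if (e.feasible && e.ic < best) {
      best = e.ic;
      s.ok = true;
      s.lambda = grid(k); s.ll = e.ll; s.trsum = e.trsum; s.ic = e.ic;
    }
  }
  return s;
}

// Continuous search: locate the positive-definiteness boundary by bisection
// on the log scale, then minimize the criterion by golden section on
// log(lambda); finally compare with lambda = 0 if that is feasible.
static SelOut select_continuous(const ModelCtx& c, double hi)
{
  SelOut s;
  s.ok = false;
  if (!(hi > 0)) return s;
  if (!eval_lambda(c, hi, true).feasible) return s;

  double lo = hi * 1e-7;
  bool lo_feas = eval_lambda(c, lo, true).feasible;
  if (!lo_feas) {
    // 12 halvings of the log-interval locate the boundary to ~0.3%
    double a = lo, b = hi;
    for (int it = 0; it < 12; ++it) {
      double m = std::sqrt(a * b);
      if (eval_lambda(c, m, true).feasible) b = m; else a = m;
    }
    lo = b;
  }

  const double gr = 0.618033988749895;
  double A = std::log(lo), Bb = std::log(hi);
  double x1 = Bb - gr * (Bb - A), x2 = A + gr * (Bb - A);
  CandEval e1 = eval_lambda(c, std::exp(x1), false);
  CandEval e2 = eval_lambda(c, std::exp(x2), false);
  double f1 = e1.feasible ? e1.ic : datum::inf;
  double f2 = e2.feasible ? e2.ic : datum::inf;
  for (int it = 0; it < 16; ++it) {
    if (f1 <= f2) {
      Bb = x2; x2 = x1; f2 = f1;
      x1 = Bb - gr * (Bb - A);
      e1 = eval_lambda(c, std::exp(x1), false);
      f1 = e1.feasible ? e1.ic : datum::inf;
    } else {
      A = x1; x1 = x2; f1 = f2;
      x2 = A + gr * (Bb - A);
      e2 = eval_lambda(c, std::exp(x2), false);
      f2 = e2.feasible ? e2.ic : datum::inf;
    }
  }
  double xbest = (f1 <= f2) ? x1 : x2;
  CandEval eb = eval_lambda(c, std::exp(xbest), false);
  if (eb.feasible) {
    s.ok = true;
    s.lambda = std::exp(xbest);
    s.ll = eb.ll; s.trsum = eb.trsum; s.ic = eb.ic;
  }
  if (lo_feas) {
    CandEval e0 = eval_lambda(c, 0.0, false);
    if (e0.feasible && (!s.ok || e0.ic < s.ic)) {
      s.ok = true;
      s.lambda = 0.0; s.ll = e0.ll; s.trsum = e0.trsum; s.ic = e0.ic;
    }
  }
  return s;
}

// Columns with at least one presence in every group under the given labels.
static uvec group_present_mask(const mat& Y, const uvec& glab, int K)
{
  const int n = Y.n_rows, p = Y.n_cols;
  mat cnt(K, p, fill::zeros);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < p; ++j)
      if (Y(i, j) > 0.5) cnt(glab(i), j) += 1.0;
  std::vector<uword> keep;
  keep.reserve(p);
  for (int j = 0; j < p; ++j) {
    bool all_present = true;
    for (int k = 0; k < K; ++k)
      if (cnt(k, j) < 0.5) { all_present = false; break; }
    if (all_present) keep.push_back(j);
  }
  return uvec(keep);
}

struct PipeOut {
  int status; // 0 ok, 1 fewer than 2 usable columns, 2/3 no feasible penalty (alt/null)
  double D;
  int p_star;
  uvec keep;
  SelOut alt, nul;
};

// The null model pools the groups, so its fit depends on the data only
// through the retained column set, not on the labels: across permutations
// the selection can be cached by that set.
typedef std::map<std::vector<uword>, SelOut> NullCache;

// One full run: per-group presence mask, penalty selection under both
// models, and the likelihood-ratio-type statistic.  `grid`/`grid0` give the
// candidate sets in grid mode; in continuous mode only their maxima are
// used as upper search bounds.
static PipeOut run_pipeline(const mat& Z, const mat& Y, const uvec& glab,
                            int K, const vec& grid, const vec& grid0,
                            bool continuous, bool penalized_ratio,
                            NullCache* cache = NULL)
{
  PipeOut o;
  o.status = 0;
  o.D = datum::nan;
  o.keep = group_present_mask(Y, glab, K);
  o.p_star = o.keep.n_elem;
  if (o.p_star < 2) { o.status = 1; return o; }
  mat Zs = Z.cols(o.keep), Ys = Y.cols(o.keep);
  const int n = Zs.n_rows, p = o.p_star;

  std::vector<uvec> vidx(n), midx(n);
  uvec nik(n);
  for (int i = 0; i < n; ++i) {
    std::vector<uword> vi, mi;
    for (int j = 0; j < p; ++j)
      (Ys(i, j) > 0.5 ? vi : mi).push_back(j);
    vidx[i] = uvec(vi);
    midx[i] = uvec(mi);
    nik(i) = vi.size();
  }

  ModelCtx ca = build_ctx(Zs, Ys, glab, K, false, vidx, midx, nik);
  o.alt = continuous ? select_continuous(ca, grid.max())
                     : select_grid(ca, grid);
  if (!o.alt.ok) { o.status = 2; return o; }

  std::vector<uword> key;
  if (cache) key = conv_to<std::vector<uword> >::from(o.keep);
  NullCache::const_iterator hit =
    cache ? cache->find(key) : NullCache::const_iterator();
  if (cache && hit != cache->end()) {
    o.nul = hit->second;
  } else {
    ModelCtx c0 = build_ctx(Zs, Ys, glab, K, true, vidx, midx, nik);
    o.nul = continuous ? select_continuous(c0, grid0.max())
                       : select_grid(c0, grid0);
    if (cache) (*cache)[key] = o.nul;
  }
  if (!o.nul.ok) { o.status = 3; return o; }

  if (penalized_ratio) {
    // P(lambda, Sigma_hat) = lambda * sum_i tr(Sigma_V^{-1}) for scalar lambda
    const double lp1 = o.alt.ll - 0.5 * o.alt.lambda * o.alt.trsum;
    const double lp0 = o.nul.ll - 0.5 * o.nul.lambda * o.nul.trsum;
    o.D = -2.0 * (lp0 - lp1);
  } else {
    o.D = -2.0 * (o.nul.ll - o.alt.ll);
  }
  return o;
}

// [[Rcpp::export]]
List scman_pipeline_cpp(const arma::mat& Z, const arma::mat& Y,
                        const arma::uvec& glab, int K,
                        const arma::vec& grid, const arma::vec& grid0,
                        bool continuous, bool penalized_ratio)
{
  PipeOut o = run_pipeline(Z, Y, glab, K, grid, grid0, continuous,
                           penalized_ratio);
  List out = List::create(
    _["status"] = o.status,
    _["D"]      = o.D,
    _["p_star"] = o.p_star,
    _["keep"]   = (o.p_star > 0)
      ? IntegerVector(wrap(conv_to<ivec>::from(o.keep + 1)))
      : IntegerVector(0));
  if (o.alt.ok) {
    out["lambda"] = o.alt.lambda;
    out["ll"]     = o.alt.ll;
    out["trsum"]  = o.alt.trsum;
    out["ic"]     = o.alt.ic;
  }
  if (o.status == 0) {
    out["lambda0"] = o.nul.lambda;
    out["ll0"]     = o.nul.ll;
    out["trsum0"]  = o.nul.trsum;
    out["ic0"]     = o.nul.ic;
  }
  return out;
}

// [[Rcpp::export]]
List scman_perm_cpp(const arma::mat& Z, const arma::mat& Y,
                    const arma::uvec& glab, int K,
                    const arma::umat& perms,
                    const arma::vec& grid, const arma::vec& grid0,
                    bool continuous, bool penalized_ratio)
{
  const int B = perms.n_cols;
  NumericVector D(B);
  IntegerVector status(B);
  NullCache cache;
  for (int b = 0; b < B; ++b) {
    if (b % 32 == 0) Rcpp::checkUserInterrupt();
    uvec gl = glab.elem(perms.col(b) - 1);
    PipeOut o = run_pipeline(Z, Y, gl, K, grid, grid0, continuous,
                             penalized_ratio, &cache);
    D[b] = (o.status == 0) ? o.D : NA_REAL;
    status[b] = o.status;
  }
  return List::create(_["D"] = D, _["status"] = status);
}

// Grid evaluation for one model without any column masking; preconditions
// (pairwise support, per-group presences under the alternative) are checked
// at the R level.
// [[Rcpp::export]]
List scman_eval_grid_cpp(const arma::mat& Z, const arma::mat& Y,
                         const arma::uvec& glab, int K,
                         bool null_model, const arma::vec& grid)
{
  const int n = Z.n_rows, p = Z.n_cols;
  std::vector<uvec> vidx(n), midx(n);
  uvec nik(n);
  for (int i = 0; i < n; ++i) {
    std::vector<uword> vi, mi;
    for (int j = 0; j < p; ++j)
      (Y(i, j) > 0.5 ? vi : mi).push_back(j);
    vidx[i] = uvec(vi);
    midx[i] = uvec(mi);
    nik(i) = vi.size();
  }
  ModelCtx c = build_ctx(Z, Y, glab, K, null_model, vidx, midx, nik);
  const int nc = grid.n_elem;
  NumericVector ic(nc), ll(nc), trsum(nc);
  LogicalVector feas(nc);
  int best = -1;
  double bic = R_PosInf;
  for (int k = 0; k < nc; ++k) {
    CandEval e = eval_lambda(c, grid(k), false);
    feas[k] = e.feasible;
    ic[k] = e.ic; ll[k] = e.ll; trsum[k] = e.trsum;
    if (e.feasible && e.ic < bic) { bic = e.ic; best = k; }
  }
  return List::create(_["feasible"] = feas, _["ic"] = ic, _["ll"] = ll,
                      _["trsum"] = trsum, _["best"] = best + 1);
}
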