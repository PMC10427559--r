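#' Lipid-dependent rate-modulating functions
#'
#' A `rate_modulation` describes how the reference rate of one macrophage
#' behaviour (apoptosis, emigration or proliferation) varies with the
#' dimensionless ingested lipid load `a >= 1`. Three functional forms are
#' supported:
#'
#' * `"constant"` -- the behaviour is lipid-independent, `g(a) = 1`.
#' * `"saturating"` -- a monotone Hill-type form
#'   `g(a) = ((a_half - 1)^n + limit (a - 1)^n) / ((a_half - 1)^n + (a - 1)^n)`
#'   running from `g(1) = 1` to `limit` as `a` grows, with half-way value
#'   `(1 + limit)/2` attained at `a = a_half`.
#' * `"peaked"` -- a non-monotone form that rises from a floor value at
#'   `a = 1` to a peak of exactly 1 at an intermediate lipid load and falls
#'   back towards the floor as `a` grows:
#'   `g(a) = floor + (1 - floor) h(a - 1) / h(x*)` with
#'   `h(x) = x^k / (b^q + x^q)` and peak offset `x* = b (k/(q - k))^(1/q)`.
#'
#' A multiplicative `scaling` may be attached; how it is applied depends on
#' the behaviour (see [eval_modulation()]).
#'
#' @param behaviour one of `"apoptosis"`, `"emigration"`, `"proliferation"`.
#' @param form one of `"constant"`, `"saturating"`, `"peaked"`.
#' @param a_half saturating form: lipid load of half-maximal change
#'   (`a_half > 1`).
#' @param limit saturating form: the limit of `g` as `a -> Inf`
#'   (`limit >= 0`).
#' @param exponent saturating form: Hill exponent (`>= 1`).
#' @param floor peaked form: value at `a = 1` and limit as `a -> Inf`
#'   (`0 <= floor < 1`).
#' @param scale_loc peaked form: location parameter `b > 0` setting where the
#'   peak sits (`a_peak = 1 + b (k/(q - k))^(1/q)`).
#' @param rise_exp peaked form: exponent `k >= 1` controlling the rise near
#'   `a = 1`.
#' @param fall_exp peaked form: exponent `q > k` controlling the decline at
#'   large `a`.
#' @param scaling positive multiplicative scaling (default 1, i.e. unscaled).
#'
#' @return an object of class `rate_modulation`.
#' @seealso [eval_modulation()], [check_boundedness()], [scenario_modulation()]
#' @export
rate_modulation <- function(behaviour = c("apoptosis", "emigration", "proliferation"),
                            form = c("constant", "saturating", "peaked"),
                            a_half = NULL, limit = NULL, exponent = 1,
                            floor = NULL, scale_loc = NULL,
                            rise_exp = 1, fall_exp = NULL,
                            scaling = 1) {
  behaviour <- match.arg(behaviour)
  form <- match.arg(form)
  if (!is.numeric(scaling) || length(scaling) != 1L || scaling <= 0)
    stop("'scaling' must be a single positive number", call. = FALSE)
  mod <- list(behaviour = behaviour, form = form, scaling = scaling)
  if (form == "saturating") {
    if (is.null(a_half) || is.null(limit))
      stop("saturating form requires 'a_half' and 'limit'", call. = FALSE)
    if (a_half <= 1) stop("saturating form requires a_half > 1", call. = FALSE)
    if (limit < 0) stop("saturating form requires limit >= 0", call. = FALSE)
    if (exponent < 1) stop("saturating form requires exponent >= 1", call. = FALSE)
    mod$a_half <- a_half
    mod$limit <- limit
    mod$exponent <- exponent
  } else if (form == "peaked") {
    if (is.null(floor) || is.null(scale_loc) || is.null(fall_exp))
      stop("peaked form requires 'floor', 'scale_loc' and 'fall_exp'", call. = FALSE)
    if (floor < 0 || floor >= 1) stop("peaked form requires 0 <= floor < 1", call. = FALSE)
    if (scale_loc <= 0) stop("peaked form requires scale_loc > 0", call. = FALSE)
    if (rise_exp < 1) stop("peaked form requires rise_exp >= 1", call. = FALSE)
    if (fall_exp <= rise_exp)
      stop("peaked form requires fall_exp > rise_exp", call. = FALSE)
    mod$floor <- floor
    mod$scale_loc <- scale_loc
    mod$rise_exp <- rise_exp
    mod$fall_exp <- fall_exp
  }
  class(mod) <- "rate_modulation"
  mod
}

#' @export
print.rate_modulation <- function(x, ...) {
  cat(sprintf("<rate_modulation> %s, %s form", x$behaviour, x$form))
  if (x$form == "saturating")
    cat(sprintf(" (a_half=%g, limit=%g, n=%g)", x$a_half, x$limit, x$exponent))
  if (x$form == "peaked")
    cat(sprintf(" (floor=%g, b=%g, k=%g, q=%g; peak at a=%g)",
                x$floor, x$scale_loc, x$rise_exp, x$fall_exp, peak_location(x)))
  if (x$scaling != 1) cat(sprintf(", scaling=%g", x$scaling))
  cat("\n")
  invisible(x)
}

check_lipid_domain <- function(a) {
  if (any(a < 1))
    stop("lipid load 'a' must be >= 1 (dimensionless, a_0 = 1)", call. = FALSE)
}

#' Evaluate the saturating (monotone) modulating function
#'
#' `g(a) = ((a_half - 1)^n + limit (a - 1)^n) / ((a_half - 1)^n + (a - 1)^n)`,
#' without applying any scaling. Monotone from `g(1) = 1` towards `limit`.
#'
#' @param a dimensionless lipid load(s), `a >= 1`.
#' @param mod a saturating [rate_modulation()].
#' @return numeric vector of modulation factors.
#' @export
eval_saturating <- function(a, mod) {
  stopifnot(inherits(mod, "rate_modulation"))
  if (mod$form != "saturating") stop("'mod' is not of saturating form", call. = FALSE)
  check_lipid_domain(a)
  c0 <- (mod$a_half - 1)^mod$exponent
  x <- (a - 1)^mod$exponent
  (c0 + mod$limit * x) / (c0 + x)
}

peak_location <- function(mod) {
  k <- mod$rise_exp; q <- mod$fall_exp
  1 + mod$scale_loc * (k / (q - k))^(1 / q)
}

#' Evaluate the peaked (non-monotone) modulating function
#'
#' `g(a) = floor + (1 - floor) h(a - 1)/h(x*)` with
#' `h(x) = x^k/(b^q + x^q)` and `x* = b (k/(q - k))^(1/q)`, without applying
#' any scaling. Equals `floor` at `a = 1`, reaches exactly 1 at
#' `a = 1 + x*`, and decays back to `floor` as `a -> Inf`.
#'
#' @inheritParams eval_saturating
#' @param mod a peaked [rate_modulation()].
#' @return numeric vector of modulation factors in `[floor, 1]`.
#' @export
eval_peaked <- function(a, mod) {
  stopifnot(inherits(mod, "rate_modulation"))
  if (mod$form != "peaked") stop("'mod' is not of peaked form", call. = FALSE)
  check_lipid_domain(a)
  k <- mod$rise_exp; q <- mod$fall_exp; b <- mod$scale_loc
  xs <- b * (k / (q - k))^(1 / q)
  hstar <- xs^k / (b^q + xs^q)
  x <- a - 1
  h <- ifelse(x == 0 & k > 0, 0, x^k / (b^q + x^q))
  mod$floor + (1 - mod$floor) * h / hstar
}

#' Evaluate a rate modulation with its scaling applied
#'
#' Applies the behaviour-specific scaling semantics:
#' * constant form: always 1, scaling ignored;
#' * saturating apoptosis/proliferation: `scaling * g(a)`;
#' * saturating emigration: the limit parameter is divided by the scaling
#'   before multiplying, so the large-`a` limit of the scaled function equals
#'   the unscaled `limit`;
#' * peaked: only the non-constant part is scaled,
#'   `floor + scaling * (g(a) - floor)`, preserving both the value at
#'   `a = 1` and the large-`a` limit.
#'
#' @inheritParams eval_saturating
#' @param mod a [rate_modulation()].
#' @return numeric vector of effective (scaled) modulation factors.
#' @export
eval_modulation <- function(a, mod) {
  stopifnot(inherits(mod, "rate_modulation"))
  check_lipid_domain(a)
  c0 <- mod$scaling
  switch(mod$form,
    constant = rep(1, length(a)),
    saturating = {
      if (mod$behaviour == "emigration" && c0 != 1) {
        adj <- mod
        adj$limit <- mod$limit / c0
        c0 * eval_saturating(a, adj)
      } else {
        c0 * eval_saturating(a, mod)
      }
    },
    peaked = {
      g <- eval_peaked(a, mod)
      mod$floor + c0 * (g - mod$floor)
    }
  )
}

modulation_limit <- function(mod) {
  # effective (scaled) limit of g as a -> Inf
  switch(mod$form,
    constant = 1,
    saturating = if (mod$behaviour == "emigration") mod$limit else mod$scaling * mod$limit,
    peaked = mod$floor
  )
}

#' Check the boundedness condition for the live-cell population
#'
#' The live-cell population grows without bound unless
#' `g_beta(a) + gamma g_gamma(a) - rho g_rho(a) > 0` for all lipid loads
#' (with the dimensionless reference apoptosis rate equal to 1, and all
#' modulations evaluated with their scalings applied). The condition is
#' evaluated on every grid node and at the analytic `a -> Inf` limits.
#'
#' @param params a [model_parameters()] object.
#' @param grid a [make_grid()] lipid grid.
#' @return a list with elements `ok` (logical), `min_value`, and `arg_min`
#'   (the lipid load at which the minimum is attained; `Inf` if the limiting
#'   value is the minimiser).
#' @export
check_boundedness <- function(params, grid) {
  stopifnot(inherits(params, "model_parameters"), inherits(grid, "lipid_grid"))
  a <- grid$nodes
  val <- eval_modulation(a, params$mods$g_beta) +
    params$gamma * eval_modulation(a, params$mods$g_gamma) -
    params$rho * eval_modulation(a, params$mods$g_rho)
  lim <- modulation_limit(params$mods$g_beta) +
    params$gamma * modulation_limit(params$mods$g_gamma) -
    params$rho * modulation_limit(params$mods$g_rho)
  i <- which.min(val)
  if (lim < val[i]) {
    list(ok = lim > 0, min_value = lim, arg_min = Inf)
  } else {
    list(ok = val[i] > 0, min_value = val[i], arg_min = a[i])
  }
}
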