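# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Truncated normal via inverse-CDF; exact truncation, no rejection loop.
.rtnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# Linear predictor from a named coefficient vector.  Names are either
# "intercept", a column of `data`, or a product term "a:b" (columns joined
# by ":").  Used by the generator and the brute-force oracle, which share
# one structural-model parameterisation.
.lp_from_coefs <- function(coefs, data) {
  lp <- rep(0, nrow(data))
  for (nm in names(coefs)) {
    if (nm == "intercept") {
      lp <- lp + coefs[[nm]]
      next
    }
    parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
    x <- rep(1, nrow(data))
    for (p in parts) {
      if (!p %in% names(data)) {
        stop("coefficient term '", nm, "' refers to unknown column '", p, "'")
      }
      x <- x * as.numeric(data[[p]])
    }
    lp <- lp + coefs[[nm]] * x
  }
  lp
}

# Inverse-CDF draw from row-wise category probabilities (0-based levels).
# `u` is one uniform per row; `probs` an n x k matrix with rows summing to 1.
.cat_from_u <- function(u, probs) {
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = length(u), ncol = length(probs), byrow = TRUE)
  k <- ncol(probs)
  out <- integer(length(u))
  cum <- probs[, 1L]
  for (j in seq_len(k - 1L)) {
    out[u >= cum] <- j
    if (j < k - 1L) cum <- cum + probs[, j + 1L]
  }
  out
}

# Expand a 3-level m2 (0/1/2) into the indicator columns the structural
# coefficients use.
.m2_indicators <- function(m2) {
  list(m2_1 = as.numeric(m2 == 1L), m2_2 = as.numeric(m2 == 2L))
}

.is_count <- function(x) length(x) == 1L && is.finite(x) && x == round(x)

# ---- fast linear predictors -------------------------------------------
#
# The Monte Carlo engine evaluates fitted glm/lm/multinom models millions
# of times on data whose covariate columns never change; going through
# stats::predict would rebuild a model frame on every call.  These
# helpers evaluate the linear predictor directly from the coefficient
# names: each name is a ":"-separated product of either a numeric column
# or a factor-level indicator (column name immediately followed by the
# level label, as coded by model.matrix).

.parse_coef_term <- function(p, data) {
  if (p %in% names(data) && !is.factor(data[[p]])) {
    return(list(col = p, level = NULL))
  }
  hits <- NULL
  for (cn in names(data)) {
    if (is.factor(data[[cn]]) && startsWith(p, cn)) {
      lev <- substring(p, nchar(cn) + 1L)
      if (lev %in% levels(data[[cn]])) hits <- rbind(hits, c(cn, lev))
    }
  }
  if (is.null(hits)) stop("cannot map coefficient term '", p, "' to data columns")
  best <- which.max(nchar(hits[, 1L]))
  list(col = hits[best, 1L], level = hits[best, 2L])
}

.coef_plan <- function(coef_names, data) {
  lapply(coef_names, function(nm) {
    if (nm == "(Intercept)") return(list())
    lapply(strsplit(nm, ":", fixed = TRUE)[[1]], .parse_coef_term, data = data)
  })
}

.eval_lp_plan <- function(beta, plan, data) {
  n <- nrow(data)
  lp <- rep(0, n)
  for (i in seq_along(beta)) {
    b <- beta[[i]]
    if (b == 0) next
    parts <- plan[[i]]
    if (!length(parts)) {
      lp <- lp + b
      next
    }
    x <- b
    for (pt in parts) {
      x <- x * if (is.null(pt$level)) as.numeric(data[[pt$col]]) else
        as.numeric(data[[pt$col]] == pt$level)
    }
    lp <- lp + x
  }
  lp
}

# lm / binomial glm
.fast_lp <- function(fit, data) {
  beta <- stats::coef(fit)
  .eval_lp_plan(beta, .coef_plan(names(beta), data), data)
}

# multinom: probability matrix over the response levels
.fast_probs_multinom <- function(fit, data) {
  beta <- stats::coef(fit)
  if (is.null(dim(beta))) beta <- matrix(beta, nrow = 1, dimnames = list(NULL, names(beta)))
  plan <- .coef_plan(colnames(beta), data)
  lps <- lapply(seq_len(nrow(beta)), function(r) .eval_lp_plan(beta[r, ], plan, data))
  den <- 1
  for (lp in lps) den <- den + exp(lp)
  cbind(1 / den, do.call(cbind, lapply(lps, function(lp) exp(lp) / den)))
}

# Precompiled predictor closures: parse the coefficient plan once against
# a data template, then evaluate on any data with the same columns.
.lp_fun <- function(fit, template) {
  beta <- stats::coef(fit)
  plan <- .coef_plan(names(beta), template)
  function(d) .eval_lp_plan(beta, plan, d)
}

.probs_fun_multinom <- function(fit, template) {
  beta <- stats::coef(fit)
  if (is.null(dim(beta))) beta <- matrix(beta, nrow = 1, dimnames = list(NULL, names(beta)))
  plan <- .coef_plan(colnames(beta), template)
  function(d) {
    lps <- lapply(seq_len(nrow(beta)), function(r) .eval_lp_plan(beta[r, ], plan, d))
    den <- 1
    for (lp in lps) den <- den + exp(lp)
    cbind(1 / den, do.call(cbind, lapply(lps, function(lp) exp(lp) / den)))
  }
}
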