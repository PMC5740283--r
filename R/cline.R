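cline_variants <- function() c("none", "left", "right", "mirror", "both")

cline_K <- function(variant) {
  2L + 2L * switch(variant, none = 0L, left = 1L, right = 1L, mirror = 1L, both = 2L)
}

cline_par_names <- function(variant) {
  switch(variant,
         none = c("centre", "width"),
         left = c("centre", "width", "deltaL", "tauL"),
         right = c("centre", "width", "deltaR", "tauR"),
         mirror = c("centre", "width", "delta", "tau"),
         both = c("centre", "width", "deltaL", "tauL", "deltaR", "tauR"))
}

check_cline_params <- function(params, variant) {
  need <- cline_par_names(variant)
  miss <- setdiff(need, names(params))
  if (length(miss)) abort(paste("missing cline parameters:", paste(miss, collapse = ", ")))
  if (params[["width"]] <= 0) abort("width must be > 0")
  for (nm in grep("^tau", need, value = TRUE)) {
    if (params[[nm]] <= 0 || params[[nm]] > 1) abort(paste(nm, "must be in (0, 1]"))
  }
  for (nm in grep("^delta", need, value = TRUE)) {
    if (params[[nm]] < 0) abort(paste(nm, "must be >= 0"))
  }
  invisible(params)
}

# unvalidated evaluation on a positional parameter vector ordered as
# cline_par_names(variant); used inside the optimizer hot loop
cline_p_fast <- function(x, par, variant) {
  c0 <- par[[1]]; w <- par[[2]]
  p <- 1 / (1 + exp(-4 * (x - c0) / w))
  if (variant == "none") return(p)
  if (variant == "mirror") {
    dL <- par[[3]]; tL <- par[[4]]; dR <- par[[3]]; tR <- par[[4]]
  } else if (variant == "left") {
    dL <- par[[3]]; tL <- par[[4]]; dR <- NA; tR <- NA
  } else if (variant == "right") {
    dR <- par[[3]]; tR <- par[[4]]; dL <- NA; tL <- NA
  } else {
    dL <- par[[3]]; tL <- par[[4]]; dR <- par[[5]]; tR <- par[[6]]
  }
  if (!is.na(dL)) {
    xl <- c0 - dL
    idx <- x < xl
    if (any(idx)) {
      pl <- 1 / (1 + exp(-4 * (xl - c0) / w))
      p[idx] <- pl * exp(4 * tL * (x[idx] - xl) / w)
    }
  }
  if (!is.na(dR)) {
    xr <- c0 + dR
    idx <- x > xr
    if (any(idx)) {
      pr <- 1 / (1 + exp(-4 * (xr - c0) / w))
      p[idx] <- 1 - (1 - pr) * exp(-4 * tR * (x[idx] - xr) / w)
    }
  }
  pmin(pmax(p, 0), 1)
}

#' Expected focal-allele frequency under a geographic cline model
#'
#' The central cline is the sigmoid `p(x) = 1 / (1 + exp(-4 (x - c) / w))`
#' with centre `c` and width `w` (inverse maximum slope). Tail variants
#' splice exponential introgression tails onto one or both sides: beyond the
#' tail offset `delta` (km from the centre) the frequency decays towards the
#' fixed end (0 on the left, 1 on the right) with slope parameter
#' `tau` in (0, 1], continuously at the junction:
#' left, for `x < c - deltaL`: `p(c - deltaL) * exp(4 tauL (x - c + deltaL) / w)`;
#' right, for `x > c + deltaR`: `1 - (1 - p(c + deltaR)) * exp(-4 tauR (x - c - deltaR) / w)`.
#' The `mirror` variant ties the two tails to shared `(delta, tau)`.
#'
#' @param x signed transect distance(s), km.
#' @param params named list/vector: `centre`, `width`, and the tail
#'   parameters required by `variant` (`deltaL`/`tauL`, `deltaR`/`tauR`, or
#'   `delta`/`tau` for `mirror`).
#' @param variant one of `"none"`, `"left"`, `"right"`, `"mirror"`, `"both"`.
#' @return expected frequency in `[0, 1]`, same length as `x`.
#' @export
cline_frequency <- function(x, params, variant = "none") {
  variant <- match.arg(variant, cline_variants())
  params <- as.list(params)
  check_cline_params(params, variant)
  c0 <- params$centre; w <- params$width
  if (variant == "mirror") {
    params$deltaL <- params$deltaR <- params$delta
    params$tauL <- params$tauR <- params$tau
  }
  sig <- function(z) 1 / (1 + exp(-4 * (z - c0) / w))
  p <- sig(x)
  if (variant %in% c("left", "mirror", "both")) {
    xl <- c0 - params$deltaL
    pl <- sig(xl)
    idx <- x < xl
    p[idx] <- pl * exp(4 * params$tauL * (x[idx] - xl) / w)
  }
  if (variant %in% c("right", "mirror", "both")) {
    xr <- c0 + params$deltaR
    pr <- sig(xr)
    idx <- x > xr
    p[idx] <- 1 - (1 - pr) * exp(-4 * params$tauR * (x[idx] - xr) / w)
  }
  pmin(pmax(p, 0), 1)
}

#' Binomial negative log-likelihood of cline data
#'
#' `-sum_i n_i [h_i log p(x_i) + (1 - h_i) log(1 - p(x_i))]` with `p`
#' clamped to `[1e-9, 1 - 1e-9]`; `n_i` is the effective sample size per
#' locality (genotypes = loci x individuals, missing excluded) and `h_i`
#' the observed hybrid index, kept as a real fraction (weighted-Bernoulli
#' form, equal to the binomial likelihood up to a data-only constant).
#'
#' @param data tibble with columns `distance` (or `x`), `h`, `n` (or
#'   `n_genotypes`).
#' @param params,variant as in [cline_frequency()].
#' @return scalar negative log-likelihood.
#' @export
cline_negloglik <- function(data, params, variant = "none") {
  d <- normalize_cline_data(data)
  if (!all(is.finite(d$x)) || !all(is.finite(d$h)) || !all(is.finite(d$n))) {
    abort("non-finite cline data")
  }
  p <- cline_frequency(d$x, params, variant)
  p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
  -sum(d$n * (d$h * log(p) + (1 - d$h) * log(1 - p)))
}

normalize_cline_data <- function(data) {
  x <- data[["distance"]] %||% data[["x"]]
  n <- data[["n"]] %||% data[["n_genotypes"]]
  h <- data[["h"]]
  if (is.null(x) || is.null(h) || is.null(n)) {
    abort("cline data needs columns distance (or x), h, and n (or n_genotypes)")
  }
  if (any(n < 1)) abort("effective n must be >= 1 at every locality")
  if (any(h < 0 | h > 1)) abort("h must lie in [0, 1]")
  tibble::tibble(x = x, h = h, n = n)
}

#' Fit one cline model variant by multistart maximum likelihood
#'
#' Bounded local optimization (L-BFGS-B) from `restarts` start points drawn
#' over data-driven boxes (centre within the x-range, width in (0, 2 span],
#' delta in \[0, span\], tau in (0, 1\]) plus one heuristic start at the
#' observed 0.5 crossing. The best optimum is kept.
#'
#' @param data cline data (see [cline_negloglik()]).
#' @param variant model variant.
#' @param restarts number of random starts (default 20).
#' @param seed RNG seed for the starts.
#' @return object of class `cline_fit`: `variant`, `par` (named), `logLik`,
#'   `K`, `n_loc`, `AICc`, `data`, `support` (filled by [support_limits()]).
#' @export
fit_cline <- function(data, variant = "none", restarts = 20L, seed = 1L) {
  variant <- match.arg(variant, cline_variants())
  d <- normalize_cline_data(data)
  K <- cline_K(variant)
  if (nrow(d) <= K) abort(sprintf("need more localities (%d) than parameters (%d)", nrow(d), K))
  rng <- range(d$x); span <- max(diff(rng), 1e-6)
  nm <- cline_par_names(variant)
  lower <- c(centre = rng[1], width = 1e-3,
             setNames(rep(0, sum(grepl("^delta", nm))), grep("^delta", nm, value = TRUE)),
             setNames(rep(1e-3, sum(grepl("^tau", nm))), grep("^tau", nm, value = TRUE)))[nm]
  upper <- c(centre = rng[2], width = 2 * span,
             setNames(rep(span, sum(grepl("^delta", nm))), grep("^delta", nm, value = TRUE)),
             setNames(rep(1, sum(grepl("^tau", nm))), grep("^tau", nm, value = TRUE)))[nm]
  xv <- d$x; hv <- d$h; nv <- d$n
  obj <- function(par) {
    p <- cline_p_fast(xv, par, variant)
    p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
    val <- -sum(nv * (hv * log(p) + (1 - hv) * log(1 - p)))
    if (!is.finite(val)) 1e12 else val
  }
  set.seed(seed)
  # width and tau sampled on the log scale: narrow zones with shallow tails
  # occupy a tiny corner of the linear box but are the common case
  draw_start <- function() {
    st <- numeric(length(nm))
    names(st) <- nm
    st["centre"] <- runif(1, lower["centre"], upper["centre"])
    st["width"] <- exp(runif(1, log(span / 50), log(2 * span)))
    for (p in grep("^delta", nm, value = TRUE)) st[p] <- runif(1, 0, span / 2)
    for (p in grep("^tau", nm, value = TRUE)) st[p] <- exp(runif(1, log(0.02), log(1)))
    pmin(pmax(st, lower), upper)
  }
  starts <- lapply(seq_len(restarts), function(i) draw_start())
  # heuristic starts at the observed 0.5 crossing, one wide and one steep
  h0 <- d$x[which.min(abs(d$h - 0.5))]
  heur <- function(w) {
    st <- setNames(c(h0, w, rep(c(span / 10, 0.2), length.out = length(nm) - 2)), nm)
    pmin(pmax(st, lower), upper)
  }
  starts <- c(list(heur(span / 6), heur(span / 20)), starts)
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      optim(st, obj, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(factr = 1e7, maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) abort("all optimizer starts failed to converge")
  n_loc <- nrow(d)
  ll <- -best$value
  aicc <- if (n_loc - K - 1 > 0) 2 * K - 2 * ll + 2 * K * (K + 1) / (n_loc - K - 1) else Inf
  structure(list(variant = variant, par = best$par, logLik = ll, K = K,
                 n_loc = n_loc, AICc = aicc, data = d, support = NULL,
                 convergence = best$convergence),
            class = "cline_fit")
}

#' Fit all five cline variants and rank them by AICc
#'
#' `AICc = 2K - 2 logLik + 2K(K+1)/(n - K - 1)` with `n` the number of
#' localities. Variants with too few localities (`n <= K + 1`) are skipped
#' with a warning. The difference to the runner-up is reported.
#'
#' @param data cline data.
#' @param restarts,seed passed to [fit_cline()].
#' @return object of class `cline_selection`: `fits` (named list),
#'   `table` (tibble ranked by AICc with `delta_AICc` relative to the best),
#'   `best` (the winning `cline_fit`).
#' @export
select_model_aicc <- function(data, restarts = 20L, seed = 1L) {
  d <- normalize_cline_data(data)
  if (nrow(d) < 6) abort("need at least 6 localities for model selection")
  fits <- list()
  for (v in cline_variants()) {
    if (nrow(d) <= cline_K(v) + 1) {
      warn(sprintf("variant '%s' skipped: n = %d localities <= K + 1 = %d",
                   v, nrow(d), cline_K(v) + 1))
      next
    }
    fits[[v]] <- fit_cline(d, v, restarts = restarts, seed = seed)
  }
  tab <- purrr::map_dfr(fits, function(f)
    tibble::tibble(variant = f$variant, K = f$K, logLik = f$logLik, AICc = f$AICc)) |>
    dplyr::arrange(.data$AICc) |>
    dplyr::mutate(delta_AICc = .data$AICc - .data$AICc[1])
  structure(list(fits = fits, table = tab, best = fits[[tab$variant[1]]],
                 delta_to_runner_up = if (nrow(tab) > 1) tab$delta_AICc[2] else NA_real_),
            class = "cline_selection")
}

#' Two-log-likelihood-unit support limits by profile likelihood
#'
#' Profiles the log-likelihood over one parameter (re-optimizing all
#' others) and reports the interval in which the profile stays within 2
#' log-likelihood units of the maximum, located by bisection to `tol`.
#' Limits that run into the parameter bounds are returned as the bound and
#' flagged open-ended.
#'
#' @param fit a `cline_fit`.
#' @param parameter parameter name (e.g. `"centre"`).
#' @param drop log-likelihood drop defining the limit (default 2).
#' @param tol bisection tolerance (default 1e-3).
#' @return tibble (parameter, estimate, lower, upper, lower_open, upper_open).
#' @export
support_limits <- function(fit, parameter, drop = 2, tol = 1e-3) {
  stopifnot(inherits(fit, "cline_fit"))
  nm <- cline_par_names(fit$variant)
  if (!parameter %in% nm) abort(paste("no parameter", parameter, "in variant", fit$variant))
  d <- fit$data
  rng <- range(d$x); span <- max(diff(rng), 1e-6)
  bounds <- list(
    centre = c(rng[1] - span, rng[2] + span),
    width = c(1e-3, 4 * span)
  )
  for (p in grep("^delta", nm, value = TRUE)) bounds[[p]] <- c(0, 2 * span)
  for (p in grep("^tau", nm, value = TRUE)) bounds[[p]] <- c(1e-3, 1)
  free <- setdiff(nm, parameter)
  xv <- d$x; hv <- d$h; nv <- d$n
  nll_vec <- function(full) {   # full ordered as cline_par_names
    p <- cline_p_fast(xv, full, fit$variant)
    p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
    val <- -sum(nv * (hv * log(p) + (1 - hv) * log(1 - p)))
    if (!is.finite(val)) 1e12 else val
  }
  prof <- function(theta) {
    if (!length(free)) {
      full <- setNames(theta, parameter)[nm]
      return(-nll_vec(full))
    }
    obj <- function(par) {
      full <- setNames(c(par, theta), c(free, parameter))[nm]
      nll_vec(full)
    }
    st <- fit$par[free]
    lo <- vapply(free, function(p) bounds[[p]][1], 0)
    hi <- vapply(free, function(p) bounds[[p]][2], 0)
    res <- tryCatch(optim(st, obj, method = "L-BFGS-B", lower = lo, upper = hi,
                          control = list(factr = 1e7, maxit = 300)),
                    error = function(e) list(value = 1e12))
    -res$value
  }
  ll_max <- fit$logLik
  target <- ll_max - drop
  mle <- fit$par[[parameter]]
  b <- bounds[[parameter]]
  find_limit <- function(dir) {
    end <- if (dir < 0) b[1] else b[2]
    # step outward until below target (or bound reached)
    step <- max(abs(end - mle) / 32, tol)
    theta <- mle
    repeat {
      nxt <- theta + dir * step
      if ((dir < 0 && nxt <= end) || (dir > 0 && nxt >= end)) {
        if (prof(end) >= target) return(list(limit = end, open = TRUE))
        lo <- theta; hi <- end
        break
      }
      if (prof(nxt) < target) { lo <- theta; hi <- nxt; break }
      theta <- nxt
      step <- step * 2
    }
    # bisection between inside (>= target) and outside (< target)
    for (i in 1:100) {
      mid <- (lo + hi) / 2
      if (abs(hi - lo) < tol) break
      if (prof(mid) >= target) lo <- mid else hi <- mid
    }
    list(limit = (lo + hi) / 2, open = FALSE)
  }
  L <- find_limit(-1); U <- find_limit(1)
  tibble::tibble(parameter = parameter, estimate = mle,
                 lower = L$limit, upper = U$limit,
                 lower_open = L$open, upper_open = U$open)
}

#' @method tidy cline_fit
#' @export
tidy.cline_fit <- function(x, support = FALSE, ...) {
  out <- tibble::tibble(term = names(x$par), estimate = unname(x$par))
  if (support) {
    s <- purrr::map_dfr(names(x$par), function(p) support_limits(x, p))
    out <- dplyr::left_join(out, dplyr::rename(s, term = "parameter")[
      c("term", "lower", "upper", "lower_open", "upper_open")], by = "term")
  }
  out
}

#' @method glance cline_fit
#' @export
glance.cline_fit <- function(x, ...) {
  tibble::tibble(variant = x$variant, K = x$K, logLik = x$logLik,
                 AICc = x$AICc, n_loc = x$n_loc)
}

#' @method tidy cline_selection
#' @export
tidy.cline_selection <- function(x, ...) x$table

#' @method glance cline_selection
#' @export
glance.cline_selection <- function(x, ...) {
  tibble::tibble(best_variant = x$best$variant,
                 delta_to_runner_up = x$delta_to_runner_up,
                 n_loc = x$best$n_loc)
}

#' @export
print.cline_fit <- function(x, ...) {
  cat(sprintf("Geographic cline fit (variant '%s'): logLik = %.3f, AICc = %.3f\n",
              x$variant, x$logLik, x$AICc))
  print(round(x$par, 4))
  invisible(x)
}

#' @export
print.cline_selection <- function(x, ...) {
  cat("Cline model selection (AICc):\n")
  print(x$table)
  invisible(x)
}
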