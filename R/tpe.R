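# A compact Tree-structured Parzen Estimator for hyperparameter search.
# Observed trials are split into "good" (lowest objective quantile) and
# "bad"; each parameter gets a 1-d Parzen density on its transformed scale
# (log for log-uniform), candidates are drawn from the good density and
# ranked by the density ratio l(x)/g(x).  Deterministic given the RNG
# state of the caller.

tpe_space_check <- function(space) {
  if (!length(space)) stop("empty hyperparameter search space")
  for (nm in names(space)) {
    sp <- space[[nm]]
    if (sp$type %in% c("uniform", "loguniform", "int")) {
      if (!(sp$lo < sp$hi)) stop("degenerate range for parameter ", nm)
      if (sp$type == "loguniform" && sp$lo <= 0)
        stop("log-uniform range must be positive for ", nm)
    } else if (sp$type == "categorical") {
      if (length(sp$values) < 1) stop("no values for parameter ", nm)
    } else stop("unknown parameter type for ", nm)
  }
  invisible(space)
}

tpe_random <- function(space) {
  lapply(space, function(sp) switch(sp$type,
    uniform = runif(1, sp$lo, sp$hi),
    loguniform = exp(runif(1, log(sp$lo), log(sp$hi))),
    int = sample(seq(sp$lo, sp$hi), 1),
    categorical = sp$values[[sample.int(length(sp$values), 1)]]))
}

# Parzen density of one parameter from observed values on the working scale
tpe_parzen <- function(vals, sp) {
  if (sp$type == "categorical") {
    k <- length(sp$values)
    cnt <- vapply(sp$values, function(v)
      sum(vapply(vals, identical, TRUE, y = v)), 0)
    list(type = "cat", p = (cnt + 1) / sum(cnt + 1))
  } else {
    tr <- function(x) if (sp$type == "loguniform") log(x) else x
    lo <- tr(sp$lo); hi <- tr(sp$hi)
    x <- vapply(vals, function(v) tr(as.numeric(v)), 0)
    bw <- max(1.06 * sd(x) * length(x)^(-0.2), (hi - lo) / 20, 1e-8)
    list(type = "num", x = x, bw = bw, lo = lo, hi = hi)
  }
}

tpe_draw <- function(dens, sp) {
  if (dens$type == "cat") {
    sp$values[[sample.int(length(dens$p), 1, prob = dens$p)]]
  } else {
    v <- rnorm(1, sample(dens$x, 1), dens$bw)
    v <- min(max(v, dens$lo), dens$hi)
    v <- if (sp$type == "loguniform") exp(v) else v
    if (sp$type == "int") v <- as.integer(min(max(round(v), sp$lo), sp$hi))
    v
  }
}

tpe_logdens <- function(dens, sp, value) {
  if (dens$type == "cat") {
    i <- which(vapply(sp$values, identical, TRUE, y = value))
    log(dens$p[i])
  } else {
    tr <- function(x) if (sp$type == "loguniform") log(x) else x
    v <- tr(as.numeric(value))
    # Parzen mixture with a uniform floor over the box
    log(mean(dnorm(v, dens$x, dens$bw)) + 1e-12 +
          0.05 / (dens$hi - dens$lo))
  }
}

# One TPE suggestion given the observed history.
tpe_suggest <- function(space, xs, ys, n_startup = 10, n_candidates = 24,
                        gamma = 0.25) {
  n <- length(ys)
  if (n < n_startup) return(tpe_random(space))
  ng <- max(2, ceiling(gamma * n))
  ord <- order(ys)
  good <- xs[ord[seq_len(ng)]]
  bad <- xs[ord[-seq_len(ng)]]
  best <- NULL; best_score <- -Inf
  dens <- lapply(names(space), function(nm) {
    sp <- space[[nm]]
    list(g = tpe_parzen(lapply(good, `[[`, nm), sp),
         b = tpe_parzen(lapply(bad, `[[`, nm), sp))
  })
  names(dens) <- names(space)
  for (k in seq_len(n_candidates)) {
    cand <- lapply(names(space), function(nm)
      tpe_draw(dens[[nm]]$g, space[[nm]]))
    names(cand) <- names(space)
    score <- sum(vapply(names(space), function(nm)
      tpe_logdens(dens[[nm]]$g, space[[nm]], cand[[nm]]) -
        tpe_logdens(dens[[nm]]$b, space[[nm]], cand[[nm]]), 0))
    if (score > best_score) { best <- cand; best_score <- score }
  }
  best
}
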