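# Shapley attribution backends: exact TreeSHAP (double precision) for
# gradient-boosted tree ensembles, and a permutation-sampling
# approximation for the kernel and network regressors.

# Parse an xgboost booster into flat per-tree arrays for the C++ kernel.
parse_xgb_trees <- function(booster, feature_names) {
  dump <- xgboost::xgb.dump(booster, dump_format = "json", with_stats = TRUE)
  trees <- jsonlite::fromJSON(dump, simplifyVector = FALSE)
  lapply(trees, function(root) {
    nodes <- list()
    walk <- function(nd) {
      nodes[[length(nodes) + 1]] <<- nd
      if (!is.null(nd$children))
        for (ch in nd$children) walk(ch)
    }
    walk(root)
    id <- vapply(nodes, function(n) n$nodeid, 0)
    idx <- function(i) match(i, id) - 1L
    is_leaf <- vapply(nodes, function(n) is.null(n$split), TRUE)
    list(
      yes = vapply(nodes, function(n)
        if (is.null(n$split)) -1L else idx(n$yes), 0L),
      no = vapply(nodes, function(n)
        if (is.null(n$split)) -1L else idx(n$no), 0L),
      feature = vapply(nodes, function(n)
        if (is.null(n$split)) -1L
        else match(n$split, feature_names) - 1L, 0L),
      threshold = vapply(nodes, function(n)
        if (is.null(n$split)) 0 else as.numeric(n$split_condition), 0),
      cover = vapply(nodes, function(n) as.numeric(n$cover), 0),
      value = vapply(nodes, function(n)
        if (is.null(n$leaf)) 0 else as.numeric(n$leaf), 0))
  })
}

shap_tree <- function(fitted, X) {
  trees <- parse_xgb_trees(fitted$booster, fitted$features)
  Xm <- as.matrix(X[, fitted$features, drop = FALSE])
  res <- tree_shap_cpp(trees, Xm)
  phi <- res[, -ncol(res), drop = FALSE]
  colnames(phi) <- fitted$features
  base <- res[1, ncol(res)] + fitted$base_score
  pred <- tree_predict_cpp(trees, Xm) + fitted$base_score
  list(phi = phi, base_value = base, prediction = pred,
       approximate = FALSE)
}

# Permutation-sampling Shapley values for an arbitrary predictor; each
# sampled (permutation, background-row) pair contributes telescoping
# marginal effects, so the per-row sum equals f(x) - f(background) exactly
# and additivity holds after averaging.
shap_sampling <- function(predict_fun, X, n_samples = 40, seed = 1,
                          background = NULL) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  bg <- background %||% X
  with_seed(seed, {
    phi <- matrix(0, n, p, dimnames = list(NULL, colnames(X)))
    base_rows <- bg[sample.int(nrow(bg), n_samples, replace = TRUE), ,
                    drop = FALSE]
    perms <- replicate(n_samples, sample.int(p), simplify = FALSE)
    for (s in seq_len(n_samples)) {
      perm <- perms[[s]]
      b <- base_rows[s, ]
      # build the chain of hybrids for every row at once
      cur <- matrix(b, n, p, byrow = TRUE, dimnames = list(NULL, colnames(X)))
      f_prev <- predict_fun(cur)
      for (j in perm) {
        cur[, j] <- X[, j]
        f_new <- predict_fun(cur)
        phi[, j] <- phi[, j] + (f_new - f_prev) / n_samples
        f_prev <- f_new
      }
    }
    base <- mean(apply(base_rows, 1, function(b)
      predict_fun(matrix(b, 1, p, dimnames = list(NULL, colnames(X))))))
    list(phi = phi, base_value = base,
         prediction = as.vector(base + rowSums(phi)),
         approximate = TRUE)
  })
}
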