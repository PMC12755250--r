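# Independent oracles used across the suite.  Everything here is written
# the dumb, obviously-correct way (explicit formulas, exhaustive
# enumeration) so it stays independent of the code paths under test.

# small variable_table from named columns
toy_table <- function(...) {
  variable_table(do.call(cbind, list(...)))
}

# Pearson r the long way: sum of cross-products over (n-1) sd sd
oracle_pearson <- function(x, y) {
  n <- length(x)
  sum((x - mean(x)) * (y - mean(y))) /
    ((n - 1) * stats::sd(x) * stats::sd(y))
}

# OLS by explicit normal equations (X'X)^-1 X'y, intercept included
oracle_ols <- function(X, y) {
  X <- cbind(1, X)
  solve(t(X) %*% X, t(X) %*% y)[, 1L]
}

oracle_rss <- function(X, y) {
  beta <- oracle_ols(X, y)
  sum((y - cbind(1, X) %*% beta)^2)
}

# the local score formula evaluated directly, no shared code
oracle_bic <- function(rss, n, k) {
  -(n / 2) * (log(2 * pi) + 1 + log(rss / n)) - ((k + 2) / 2) * log(n)
}

# all DAGs over a node set, by brute force over the 3^(p(p-1)/2)
# orientations (none / forward / backward) of each unordered pair,
# keeping the acyclic ones.  For 3 nodes this yields 25 graphs.
all_dags <- function(nodes) {
  pairs <- t(utils::combn(nodes, 2L))
  k <- nrow(pairs)
  states <- expand.grid(rep(list(0:2), k))
  out <- list()
  for (i in seq_len(nrow(states))) {
    em <- matrix(character(0), 0L, 2L)
    for (j in seq_len(k)) {
      s <- states[i, j]
      if (s == 1) em <- rbind(em, pairs[j, ])
      if (s == 2) em <- rbind(em, rev(pairs[j, ]))
    }
    g <- tryCatch(dag_structure(nodes, em), error = function(e) NULL)
    if (!is.null(g)) out[[length(out) + 1L]] <- g
  }
  out
}

# canonical key of a DAG's Markov equivalence class: skeleton plus
# v-structures (colliders whose parents are non-adjacent)
markov_class_key <- function(dag) {
  em <- dag$edges
  skel <- sort(apply(em, 1L, function(e) paste(sort(e), collapse = "~")))
  adjacent <- function(a, b)
    any((em[, 1L] == a & em[, 2L] == b) | (em[, 1L] == b & em[, 2L] == a))
  vs <- character(0)
  for (v in dag$nodes) {
    pa <- dag_parents(dag, v)
    if (length(pa) < 2L) next
    for (cmb in utils::combn(sort(pa), 2L, simplify = FALSE))
      if (!adjacent(cmb[1L], cmb[2L]))
        vs <- c(vs, paste(cmb[1L], cmb[2L], "->", v))
  }
  paste(c(skel, "|", sort(vs)), collapse = ";")
}

# exhaustive best total score over all DAGs on few nodes
oracle_best_score <- function(data) {
  dags <- all_dags(colnames(data))
  max(vapply(dags, total_bic_score, numeric(1), data = data))
}

# all simple directed paths source -> target by plain recursive DFS
oracle_paths <- function(dag, source, target) {
  found <- list()
  walk <- function(path) {
    tip <- path[length(path)]
    if (tip == target) {
      found[[length(found) + 1L]] <<- path
      return(invisible())
    }
    for (ch in dag_children(dag, tip))
      if (!ch %in% path) walk(c(path, ch))
  }
  if (source != target) walk(source)
  found
}

# LMG by literal enumeration of all p! orderings
oracle_lmg <- function(data, outcome, predictors) {
  x <- as.matrix(unclass(data))
  y <- x[, outcome]
  tss <- sum((y - mean(y))^2)
  r2 <- function(vars) {
    if (!length(vars)) return(0)
    1 - oracle_rss(x[, vars, drop = FALSE], y) / tss
  }
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    out
  }
  shares <- stats::setNames(numeric(length(predictors)), predictors)
  orderings <- perms(predictors)
  for (ord in orderings)
    for (i in seq_along(ord))
      shares[ord[i]] <- shares[ord[i]] + r2(ord[seq_len(i)]) -
        r2(ord[seq_len(i - 1L)])
  shares / length(orderings)
}

# single-pass agglomerative average-linkage clustering on 1 - |r|,
# merging while the closest pair of clusters sits at distance <= cut
oracle_avg_linkage <- function(corr, cut) {
  d <- 1 - abs(unclass(corr))
  groups <- as.list(colnames(corr))
  repeat {
    if (length(groups) == 1L) break
    best <- c(NA, NA)
    best_d <- Inf
    for (i in seq_along(groups)) for (j in seq_along(groups)) {
      if (i >= j) next
      dd <- mean(d[groups[[i]], groups[[j]]])
      if (dd < best_d) {
        best_d <- dd
        best <- c(i, j)
      }
    }
    if (best_d > cut) break
    groups[[best[1L]]] <- c(groups[[best[1L]]], groups[[best[2L]]])
    groups[[best[2L]]] <- NULL
  }
  lapply(groups, sort)
}

# study-like ground truth as a coefficient matrix B[child, parent]
true_B <- function(tab) {
  dag <- attr(tab, "true_dag")
  co <- attr(tab, "true_coefficients")
  p <- length(dag$nodes)
  B <- matrix(0, p, p, dimnames = list(dag$nodes, dag$nodes))
  em <- dag$edges
  for (i in seq_len(nrow(em)))
    B[em[i, 2L], em[i, 1L]] <- co[paste0(em[i, 1L], "->", em[i, 2L])]
  B
}
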