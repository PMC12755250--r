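#' Fit a recursive linear path model on a learned DAG
#'
#' Every node with at least one parent is regressed on its parents by OLS.
#' For a recursive linear-Gaussian model with independent disturbances and
#' no latent variables, these equation-wise estimates are the maximum
#' likelihood path coefficients, so no joint covariance fit is needed.
#' Standard errors come from the classical OLS covariance
#' `sigma^2 (X'X)^{-1}` and two-sided p-values from the t distribution
#' with `n - k - 1` degrees of freedom.  Because the inputs are z-scored,
#' every coefficient is a standardized effect.
#'
#' @param dag a [dag_structure()] over variables of `data`.
#' @param data a standardized [variable_table()].
#' @return class `path_model`: list with `dag`, `equations` (per non-root
#'   node a data frame of term, estimate, se, statistic, p_value), `B`
#'   (p x p coefficient matrix with `B[child, parent]` = direct effect,
#'   zero where there is no edge) and `n`.
#' @export
fit_path_model <- function(dag, data) {
  stopifnot(inherits(dag, "dag"), inherits(data, "variable_table"))
  if (!all(dag$nodes %in% colnames(data)))
    stop("DAG nodes missing from data: ",
         paste(setdiff(dag$nodes, colnames(data)), collapse = ", "))
  x <- unclass_table(data)
  n <- nrow(x)
  p <- length(dag$nodes)
  B <- matrix(0, p, p, dimnames = list(dag$nodes, dag$nodes))
  equations <- list()
  for (v in dag$nodes) {
    pa <- dag_parents(dag, v)
    if (!length(pa)) next
    X <- cbind(`(Intercept)` = 1, x[, pa, drop = FALSE])
    qrx <- qr(X)
    if (qrx$rank < ncol(X))
      stop("rank-deficient design for node ", v)
    coefs <- qr.coef(qrx, x[, v])
    res <- qr.resid(qrx, x[, v])
    df <- n - length(pa) - 1L
    sigma2 <- sum(res^2) / df
    XtXinv <- chol2inv(qr.R(qrx))
    se <- sqrt(sigma2 * diag(XtXinv))
    tval <- coefs / se
    pval <- 2 * stats::pt(-abs(tval), df = df)
    equations[[v]] <- data.frame(
      term = names(coefs), estimate = unname(coefs), se = unname(se),
      statistic = unname(tval), p_value = unname(pval),
      row.names = NULL)
    B[v, pa] <- coefs[pa]
  }
  structure(list(dag = dag, equations = equations, B = B, n = n),
            class = "path_model")
}

#' @export
print.path_model <- function(x, ...) {
  cat("path_model on", length(x$dag$nodes), "nodes,",
      nrow(x$dag$edges), "edges, n =", x$n, "\n")
  for (v in names(x$equations)) {
    eq <- x$equations[[v]]
    eq <- eq[eq$term != "(Intercept)", , drop = FALSE]
    cat(" ", v, "~", paste(sprintf("%.3f*%s", eq$estimate, eq$term),
                           collapse = " + "), "\n")
  }
  invisible(x)
}

#' Enumerate all directed paths into a target node
#'
#' Breadth-first traversal from each source along out-edges: paths are
#' discovered in order of increasing length (shortest first), with
#' same-length alternatives ordered lexicographically by node name.  In a
#' DAG every directed path is simple, so the enumeration is exhaustive and
#' finite.
#'
#' @param dag a [dag_structure()].
#' @param target node name the paths must end at.
#' @return named list mapping every node to a list of paths (character
#'   vectors `c(source, ..., target)`); nodes with no path map to an
#'   empty list.  The target maps to an empty list.
#' @export
enumerate_paths <- function(dag, target) {
  stopifnot(inherits(dag, "dag"))
  if (!target %in% dag$nodes) stop("unknown target: ", target)
  out <- vector("list", length(dag$nodes))
  names(out) <- dag$nodes
  for (s in dag$nodes) {
    found <- list()
    if (s != target) {
      queue <- list(s)  # FIFO of partial paths from s
      while (length(queue)) {
        path <- queue[[1L]]
        queue <- queue[-1L]
        tip <- path[length(path)]
        for (ch in sort(dag_children(dag, tip))) {
          nxt <- c(path, ch)
          if (ch == target) found[[length(found) + 1L]] <- nxt
          else queue[[length(queue) + 1L]] <- nxt
        }
      }
    }
    out[[s]] <- found
  }
  out
}

#' Direct, indirect and total effects on a target
#'
#' The total effect of a source on the target is the sum over all directed
#' paths of the product of edge coefficients along the path.  It is
#' computed twice — by explicit path enumeration and as the
#' `(target, source)` entry of `(I - B)^{-1} - I`, which for a DAG is the
#' finite series `B + B^2 + ... + B^p` (B is nilpotent) — and the two
#' routes must agree to `tol` or an error is raised.  The indirect effect
#' is total minus direct.
#'
#' @param model a [fit_path_model()] result.
#' @param target name of the target (outcome) node.
#' @param tol agreement tolerance between the two computations.
#' @return class `effect_table`: data frame with one row per source node
#'   (all nodes except the target): source, target, direct, se, p_value
#'   (of the direct edge; NA when absent), indirect, total.  The list of
#'   contributing paths, with their coefficient products, is attached as
#'   attribute `paths`.
#' @export
total_effects <- function(model, target, tol = 1e-10) {
  stopifnot(inherits(model, "path_model"))
  dag <- model$dag
  if (!target %in% dag$nodes) stop("unknown target: ", target)
  B <- model$B
  p <- nrow(B)
  Tm <- solve(diag(p) - B) - diag(p)
  dimnames(Tm) <- dimnames(B)
  paths <- enumerate_paths(dag, target)
  sources <- setdiff(dag$nodes, target)
  path_rows <- list()
  rows <- lapply(sources, function(s) {
    pr <- vapply(paths[[s]], function(pth) {
      prod(B[cbind(pth[-1L], pth[-length(pth)])])
    }, numeric(1))
    total_paths <- sum(pr)
    total_mat <- Tm[target, s]
    if (abs(total_paths - total_mat) > tol)
      stop("path-sum total effect (", total_paths,
           ") disagrees with (I - B)^{-1} - I (", total_mat,
           ") for source ", s)
    if (length(pr))
      path_rows[[s]] <<- data.frame(
        source = s,
        path = vapply(paths[[s]], paste, character(1), collapse = "->"),
        path_product = pr)
    direct <- B[target, s]
    se <- NA_real_; pv <- NA_real_
    eq <- model$equations[[target]]
    if (direct != 0 && !is.null(eq)) {
      i <- match(s, eq$term)
      se <- eq$se[i]; pv <- eq$p_value[i]
    }
    data.frame(source = s, target = target, direct = direct, se = se,
               p_value = pv, indirect = total_mat - direct,
               total = total_mat)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "paths") <- if (length(path_rows))
    do.call(rbind, c(path_rows, list(make.row.names = FALSE)))
  else data.frame(source = character(0), path = character(0),
                  path_product = numeric(0))
  class(out) <- c("effect_table", "data.frame")
  out
}

#' @export
print.effect_table <- function(x, digits = 4L, ...) {
  y <- as.data.frame(x)
  y[c("direct", "indirect", "total")] <-
    lapply(y[c("direct", "indirect", "total")], round, digits)
  print(y)
  invisible(x)
}

#' Write an effect table and its path report as TSV
#' @param effects an [total_effects()] result.
#' @param path destination for the effects table.
#' @param paths_path optional destination for the per-path report
#'   (source, arrow-joined path, coefficient product).
#' @return `path`, invisibly.
#' @export
write_effects <- function(effects, path, paths_path = NULL) {
  stopifnot(inherits(effects, "effect_table"))
  utils::write.table(as.data.frame(effects), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  if (!is.null(paths_path))
    utils::write.table(attr(effects, "paths"), paths_path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export structural equations as plain text
#'
#' One `child ~ parent1 + parent2 + ...` line per non-root node, the
#' syntax accepted by most SEM software.
#'
#' @param dag a [dag_structure()].
#' @param path destination file, or `NULL` to return the lines.
#' @return the lines, invisibly if written to `path`.
#' @export
write_equations <- function(dag, path = NULL) {
  stopifnot(inherits(dag, "dag"))
  lines <- character(0)
  for (v in dag$nodes) {
    pa <- dag_parents(dag, v)
    if (length(pa))
      lines <- c(lines, paste(v, "~", paste(pa, collapse = " + ")))
  }
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}
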