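#' Specify a linear-Gaussian structural equation model
#'
#' @param dag a [dag_structure()].
#' @param coefficients named numeric vector of edge coefficients, named by
#'   `"from->to"` strings; the names must match the DAG's edge set
#'   exactly.
#' @param noise_sd named numeric vector of per-node noise standard
#'   deviations (all positive), or `NULL` to auto-solve every noise
#'   variance so that each node has unit marginal variance (see
#'   [unit_variance_noise()]).
#' @param n sample count.
#' @param seed integer seed.
#' @return class `sem_specification`.
#' @export
sem_specification <- function(dag, coefficients, noise_sd = NULL, n,
                              seed = 1L) {
  stopifnot(inherits(dag, "dag"))
  keys <- dag_edge_strings(dag)
  if (!setequal(names(coefficients), keys) ||
      length(coefficients) != length(keys))
    stop("coefficient names must match the DAG edge set exactly")
  if (any(!is.finite(coefficients))) stop("non-finite coefficient")
  if (is.null(noise_sd)) {
    noise_sd <- unit_variance_noise(dag, coefficients)
  } else {
    if (!setequal(names(noise_sd), dag$nodes))
      stop("noise_sd must be named by every node")
    if (any(noise_sd <= 0)) stop("all noise_sd must be positive")
  }
  if (n < 3L) stop("n must be at least 3")
  structure(list(dag = dag, coefficients = coefficients,
                 noise_sd = noise_sd[dag$nodes], n = as.integer(n),
                 seed = as.integer(seed)),
            class = "sem_specification")
}

#' Solve noise standard deviations for unit marginal variances
#'
#' Walks the DAG in topological order, accumulating the implied
#' covariance matrix, and sets each node's noise variance to
#' `1 - beta' Sigma_parents beta`.  Errors if the edge coefficients force
#' a node's structural variance to 1 or more, which would require
#' non-positive noise.
#'
#' @param dag a [dag_structure()].
#' @param coefficients named numeric vector as in [sem_specification()].
#' @return named numeric vector of noise standard deviations.
#' @export
unit_variance_noise <- function(dag, coefficients) {
  ord <- topological_sort(dag)
  p <- length(ord)
  Sigma <- matrix(0, p, p, dimnames = list(ord, ord))
  sds <- stats::setNames(numeric(p), ord)
  for (v in ord) {
    pa <- dag_parents(dag, v)
    beta <- coefficients[paste0(pa, "->", v)]
    sv <- if (length(pa))
      drop(crossprod(beta, Sigma[pa, pa, drop = FALSE] %*% beta))
    else 0
    if (sv >= 1)
      stop("structural variance of ", v, " is ", signif(sv, 4),
           " >= 1; cannot reach unit marginal variance")
    sds[v] <- sqrt(1 - sv)
    # cross-covariances with everything generated so far
    if (length(pa))
      Sigma[v, ] <- Sigma[, v] <- drop(Sigma[, pa, drop = FALSE] %*% beta)
    Sigma[v, v] <- 1
  }
  sds
}

# analytic covariance implied by a spec: (I - B)^-1 D (I - B)^-T
sem_covariance <- function(spec) {
  ord <- topological_sort(spec$dag)
  p <- length(ord)
  Bm <- matrix(0, p, p, dimnames = list(ord, ord))
  em <- spec$dag$edges
  for (i in seq_len(nrow(em)))
    Bm[em[i, 2L], em[i, 1L]] <-
      spec$coefficients[paste0(em[i, 1L], "->", em[i, 2L])]
  inv <- solve(diag(p) - Bm)
  S <- inv %*% diag(spec$noise_sd[ord]^2, p) %*% t(inv)
  dimnames(S) <- list(ord, ord)
  S[spec$dag$nodes, spec$dag$nodes]
}

#' Simulate data from a linear-Gaussian structural model
#'
#' Nodes are generated in topological order as the coefficient-weighted
#' sum of their parents plus independent Gaussian noise; deterministic
#' under the spec's seed.
#'
#' @param spec a [sem_specification()].
#' @param roles optional named roles vector passed to [variable_table()].
#' @param rescale if `TRUE`, divide each column by its analytic (not
#'   sample) standard deviation so the population variances are exactly 1.
#' @return a [variable_table()] (columns in the DAG's node order) with
#'   attributes `true_dag` and `true_coefficients` recording the ground
#'   truth.
#' @export
simulate_sem <- function(spec, roles = NULL, rescale = FALSE) {
  stopifnot(inherits(spec, "sem_specification"))
  set.seed(spec$seed)
  ord <- topological_sort(spec$dag)
  n <- spec$n
  x <- matrix(0, n, length(ord), dimnames = list(NULL, ord))
  for (v in ord) {
    pa <- dag_parents(spec$dag, v)
    mu <- if (length(pa))
      x[, pa, drop = FALSE] %*% spec$coefficients[paste0(pa, "->", v)]
    else 0
    x[, v] <- mu + stats::rnorm(n, 0, spec$noise_sd[v])
  }
  x <- x[, spec$dag$nodes, drop = FALSE]
  if (rescale) {
    S <- sem_covariance(spec)
    x <- sweep(x, 2L, sqrt(diag(S)[colnames(x)]), "/")
  }
  out <- variable_table(x, roles = roles)
  attr(out, "true_dag") <- spec$dag
  attr(out, "true_coefficients") <- spec$coefficients
  out
}

#' Study-like synthetic fixture
#'
#' An 8-variable linear-Gaussian model emulating the structure of the
#' substance-use / parental-problems / polygenic-score / externalizing
#' system the framework targets: three inter-linked parental substance-use
#' factors (Tobacco, Drug, Alcohol) feed two parental-problem factors
#' (EmoIssues, Behavioral), which in turn drive a somatic-complaints
#' factor; the child's polygenic score (PRS) is weakly downstream of
#' parental behavior (genetic-nurture correlations of a few hundredths,
#' so a marginal outcome-on-PRS regression stays near the direct 0.07)
#' and the
#' externalizing outcome (External) receives direct effects
#' Alcohol 0.33, EmoIssues 0.20, Behavioral 0.10 and PRS 0.07.  All
#' noise variances are solved so every variable has unit marginal
#' variance, making the edge coefficients standardized effects.
#'
#' @param n sample count (>= 500).
#' @param seed integer seed.
#' @return a [variable_table()] with roles `outcome = External`,
#'   `genetic = PRS`, and ground-truth attributes as in [simulate_sem()].
#' @export
make_study_like <- function(n = 10000L, seed = 1L) {
  if (n < 500L) stop("n must be at least 500")
  spec <- sem_specification(study_like_dag(), study_like_coefficients(),
                            noise_sd = NULL, n = n, seed = seed)
  simulate_sem(spec, roles = c(External = "outcome", PRS = "genetic"))
}

#' Ground-truth DAG of the study-like fixture
#' @return a [dag_structure()] over the 8 fixture variables.
#' @export
study_like_dag <- function() {
  dag_structure(
    c("Tobacco", "Drug", "Alcohol", "EmoIssues", "Behavioral", "Somatic",
      "PRS", "External"),
    names(study_like_coefficients()))
}

#' Ground-truth coefficients of the study-like fixture
#' @return named numeric vector of edge coefficients (`"from->to"`).
#' @export
study_like_coefficients <- function() {
  c("Tobacco->Drug" = 0.30,
    "Tobacco->Alcohol" = 0.20,
    "Drug->Alcohol" = 0.40,
    "Alcohol->EmoIssues" = 0.50,
    "Drug->EmoIssues" = 0.15,
    "EmoIssues->Behavioral" = 0.50,
    "Alcohol->Behavioral" = 0.20,
    "EmoIssues->Somatic" = 0.40,
    "Behavioral->PRS" = 0.03,
    "Alcohol->External" = 0.33,
    "EmoIssues->External" = 0.20,
    "Behavioral->External" = 0.10,
    "PRS->External" = 0.07)
}

#' Block-equicorrelated Gaussian table
#'
#' Multivariate normal draws whose population correlation matrix has
#' equicorrelated blocks: `within_r` inside each block, `between_r`
#' across blocks.  Columns are z-scored before return.  Used as a fixture
#' for the clustering and aggregation steps.
#'
#' @param block_sizes integer vector of block sizes.
#' @param within_r within-block correlation.
#' @param between_r between-block correlation (default 0).
#' @param n sample count.
#' @param seed integer seed.
#' @return a [variable_table()] with variables `B<i>V<j>`; the block
#'   partition is attached as attribute `blocks`.
#' @export
make_correlated_blocks <- function(block_sizes, within_r, between_r = 0,
                                   n = 1000L, seed = 1L) {
  p <- sum(block_sizes)
  block_of <- rep(seq_along(block_sizes), block_sizes)
  Sigma <- matrix(between_r, p, p)
  for (bl in seq_along(block_sizes)) {
    i <- which(block_of == bl)
    Sigma[i, i] <- within_r
  }
  diag(Sigma) <- 1
  R <- tryCatch(chol(Sigma), error = function(e)
    stop("implied correlation matrix is not positive definite ",
         "(within_r = ", within_r, ", between_r = ", between_r, ")"))
  set.seed(seed)
  z <- matrix(stats::rnorm(n * p), n, p) %*% R
  nm <- paste0("B", block_of, "V",
               unlist(lapply(block_sizes, seq_len)))
  colnames(z) <- nm
  out <- standardize(variable_table(z))
  attr(out, "blocks") <- split(nm, block_of)
  out
}
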