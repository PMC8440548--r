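#' Species-level trait means from individual records
#'
#' @param table Data frame of individual records with a `species` column.
#' @param trait Name of the trait column to average.
#' @return A named numeric vector of per-species arithmetic means with an
#'   `n_per_species` attribute giving the number of non-missing individuals
#'   used per species. Species with no non-missing values are dropped with a
#'   message.
#' @export
species_means <- function(table, trait) {
  if (!nrow(table)) stop("empty trait table")
  if (!trait %in% names(table)) stop("trait column not found: ", trait)
  if (!"species" %in% names(table)) stop("trait table needs a 'species' column")
  x <- table[[trait]]
  sp <- as.character(table$species)
  ok <- !is.na(x)
  n_all <- table(sp)
  n_ok <- tapply(ok, sp, sum)
  dropped <- names(n_ok)[n_ok == 0]
  if (length(dropped)) {
    message("dropping species with no non-missing '", trait, "' values: ",
            paste(dropped, collapse = ", "))
  }
  m <- tapply(x[ok], sp[ok], mean)
  out <- as.numeric(m)
  names(out) <- names(m)
  attr(out, "n_per_species") <- as.integer(n_ok[names(m)])
  out
}

# Align a named trait vector with a covariance matrix; returns list(y, C).
align_trait_cov <- function(values, C) {
  taxa <- intersect(names(values), rownames(C))
  if (length(taxa) < length(values)) {
    message("dropping ", length(values) - length(taxa),
            " species absent from the covariance matrix")
  }
  if (length(taxa) < 4L) stop("need at least 4 taxa shared between trait and covariance")
  list(y = values[taxa], C = C[taxa, taxa, drop = FALSE])
}

# Profile log-likelihood of a Brownian/lambda model: y ~ N(mu 1, s2 * V),
# with mu and s2 profiled out by GLS. Returns the maximized log-likelihood.
profile_loglik_lambda <- function(y, C, lambda) {
  V <- lambda_transform(C, lambda)
  n <- length(y)
  U <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(U)) stop("singular lambda-transformed covariance at lambda = ", lambda)
  one <- rep(1, n)
  Vi_y <- backsolve(U, forwardsolve(t(U), y))
  Vi_1 <- backsolve(U, forwardsolve(t(U), one))
  mu <- sum(Vi_y) / sum(Vi_1)
  r <- y - mu
  Vi_r <- Vi_y - mu * Vi_1
  s2 <- sum(r * Vi_r) / n
  if (s2 <= 0) stop("degenerate trait variance")
  logdet <- 2 * sum(log(diag(U)))
  -0.5 * (n * log(2 * pi * s2) + logdet + n)
}

#' Maximum-likelihood estimate of Pagel's lambda
#'
#' Estimates the strength of phylogenetic signal in species means as the
#' multiplier `lambda` on off-diagonal phylogenetic covariances that
#' maximises the Gaussian likelihood, with the phylogenetic mean and rate
#' profiled out by generalized least squares at each candidate `lambda`.
#' The search is a bounded scalar optimization on `[0, 1]` (tolerance 1e-6),
#' with both endpoints checked explicitly.
#'
#' @param values Named numeric vector of species means (see [species_means()]).
#' @param C Phylogenetic covariance matrix (see [phylo_vcv()]).
#' @return A `signal_estimate` list: `statistic` ("lambda"), `estimate`,
#'   `loglik`, `p_randomization` (NA until [signal_randomization_test()] is
#'   run) and `unidentifiable` (TRUE on a star phylogeny, where the
#'   likelihood is flat in lambda and 0 is returned by convention).
#' @export
pagels_lambda_ml <- function(values, C) {
  al <- align_trait_cov(values, C)
  y <- as.numeric(al$y); Cm <- al$C
  if (stats::var(y) <= 0) stop("zero trait variance across species")
  off <- Cm; diag(off) <- 0
  if (max(abs(off)) < 1e-12 * max(diag(Cm))) {
    return(new_signal_estimate("lambda", 0,
                               loglik = profile_loglik_lambda(y, Cm, 0),
                               unidentifiable = TRUE))
  }
  f <- function(l) profile_loglik_lambda(y, Cm, l)
  opt <- stats::optimize(f, interval = c(0, 1), maximum = TRUE, tol = 1e-6)
  cand <- c(0, opt$maximum, 1)
  ll <- vapply(cand, f, numeric(1))
  i <- which.max(ll)
  new_signal_estimate("lambda", cand[i], loglik = ll[i])
}

#' Blomberg's K statistic for phylogenetic signal
#'
#' K compares the observed ratio of tip variance around the phylogenetic
#' (GLS) mean to the phylogenetically corrected error variance against its
#' Brownian-motion expectation on the same tree; K is calibrated to 1 under
#' Brownian motion, with larger values indicating stronger signal.
#'
#' @inheritParams pagels_lambda_ml
#' @return A `signal_estimate` list with `statistic = "K"`.
#' @export
blombergs_K <- function(values, C) {
  al <- align_trait_cov(values, C)
  est <- K_statistic(as.numeric(al$y), solve_cov(al$C), al$C)
  new_signal_estimate("K", est)
}

solve_cov <- function(C) {
  out <- tryCatch(chol2inv(chol(C)), error = function(e) NULL)
  if (is.null(out)) stop("singular phylogenetic covariance matrix")
  dimnames(out) <- dimnames(C)
  out
}

# Direct K formula given precomputed C^{-1}; reused by the randomization test.
K_statistic <- function(y, Cinv, C) {
  n <- length(y)
  one <- rep(1, n)
  denom1 <- as.numeric(one %*% Cinv %*% one)
  a_hat <- as.numeric(one %*% Cinv %*% y) / denom1
  r <- y - a_hat
  mse0 <- sum(r * r) / (n - 1)
  mse <- as.numeric(r %*% Cinv %*% r) / (n - 1)
  if (mse <= 0) stop("degenerate trait variance")
  expected <- (sum(diag(C)) - n / denom1) / (n - 1)
  (mse0 / mse) / expected
}

new_signal_estimate <- function(statistic, estimate, loglik = NA_real_,
                                p_randomization = NA_real_,
                                unidentifiable = FALSE) {
  structure(list(statistic = statistic, estimate = estimate, loglik = loglik,
                 p_randomization = p_randomization,
                 unidentifiable = unidentifiable),
            class = "signal_estimate")
}

#' @export
print.signal_estimate <- function(x, ...) {
  cat(sprintf("%s = %.4f", x$statistic, x$estimate))
  if (is.finite(x$loglik)) cat(sprintf("  (logLik %.3f)", x$loglik))
  if (!is.na(x$p_randomization)) cat(sprintf("  p = %.4f", x$p_randomization))
  if (isTRUE(x$unidentifiable)) cat("  [unidentifiable: star phylogeny]")
  cat("\n")
  invisible(x)
}

#' Randomization test for phylogenetic signal
#'
#' Shuffles trait values across the tips of the phylogeny `n_perm` times and
#' compares the observed statistic to the permutation distribution. The
#' p-value uses the add-one estimator `(1 + #(perm >= obs)) / (1 + n_perm)`,
#' so it is never exactly zero.
#'
#' @inheritParams pagels_lambda_ml
#' @param statistic `"lambda"` or `"K"`.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed; the same seed reproduces the same p-value.
#' @return A `signal_estimate` with `p_randomization` filled in.
#' @export
signal_randomization_test <- function(values, C, statistic = c("lambda", "K"),
                                      n_perm = 999, seed = 1L) {
  statistic <- match.arg(statistic)
  stopifnot(n_perm >= 1)
  al <- align_trait_cov(values, C)
  y <- as.numeric(al$y); Cm <- al$C
  if (statistic == "K") {
    Cinv <- solve_cov(Cm)
    stat_fun <- function(v) K_statistic(v, Cinv, Cm)
  } else {
    stat_fun <- function(v) {
      names(v) <- rownames(Cm)
      pagels_lambda_ml(v, Cm)$estimate
    }
  }
  obs <- stat_fun(y)
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) stat_fun(sample(y)), numeric(1))
  p <- (1 + sum(perm >= obs)) / (1 + n_perm)
  out <- if (statistic == "lambda") pagels_lambda_ml(al$y, Cm) else blombergs_K(al$y, Cm)
  out$p_randomization <- p
  out
}

#' Individual-level bootstrap of a phylogenetic-signal statistic
#'
#' Individual counts per species vary widely in field collections, so the
#' species mean itself is an estimate. Each bootstrap iteration resamples,
#' within every species, that species' individuals with replacement to the
#' same count, recomputes species means, and recomputes the signal statistic.
#' Iteration `i` seeds the RNG with `seed + i`, so bootstrap distributions
#' computed for different groups from the same base seed are pairable by
#' iteration index.
#'
#' @inheritParams species_means
#' @param C Phylogenetic covariance matrix covering the species in `table`.
#' @param statistic `"lambda"` or `"K"`.
#' @param n_iter Number of bootstrap iterations (default 1000).
#' @param seed Integer base seed.
#' @param group_label Label attached to the result (e.g. a region name).
#' @return A `bootstrap_distribution` list: `statistic`, `draws`, `n_iter`,
#'   `group_label`.
#' @export
bootstrap_signal <- function(table, trait, C, statistic = c("lambda", "K"),
                             n_iter = 1000, seed = 1L, group_label = "full") {
  statistic <- match.arg(statistic)
  stopifnot(n_iter >= 1)
  if (!nrow(table)) stop("empty trait table")
  x <- table[[trait]]
  sp <- as.character(table$species)
  keep <- !is.na(x)
  x <- x[keep]; sp <- sp[keep]
  idx_by_sp <- split(seq_along(x), sp)
  taxa <- intersect(names(idx_by_sp), rownames(C))
  if (length(taxa) < 4L) stop("need at least 4 species present in the covariance matrix")
  idx_by_sp <- idx_by_sp[taxa]
  Cm <- C[taxa, taxa, drop = FALSE]
  stat_fun <- if (statistic == "lambda") {
    function(m) pagels_lambda_ml(m, Cm)$estimate
  } else {
    Cinv <- solve_cov(Cm)
    function(m) K_statistic(as.numeric(m), Cinv, Cm)
  }
  draws <- numeric(n_iter)
  for (i in seq_len(n_iter)) {
    set.seed(seed + i)
    m <- vapply(idx_by_sp, function(ii) {
      mean(x[ii[sample.int(length(ii), replace = TRUE)]])
    }, numeric(1))
    draws[i] <- stat_fun(m)
  }
  structure(list(statistic = statistic, draws = draws, n_iter = n_iter,
                 group_label = group_label),
            class = "bootstrap_distribution")
}

#' Compare bootstrap distributions of a signal statistic between groups
#'
#' Summarises two bootstrap distributions (mean, SD) and reports the
#' proportion of iteration-paired draws in which group `a` exceeds group `b`.
#' The pair of groups is flagged `separated` when that proportion is at least
#' 0.975 or at most 0.025 (i.e. the paired bootstrap puts at least 95%
#' one-sided mass on a consistent ordering).
#'
#' @param a,b `bootstrap_distribution` objects for the same statistic.
#' @return A one-row data frame with group means, SDs, `prop_a_gt_b`, and
#'   `separated`.
#' @export
compare_signal_groups <- function(a, b) {
  stopifnot(inherits(a, "bootstrap_distribution"),
            inherits(b, "bootstrap_distribution"))
  if (!length(a$draws) || !length(b$draws)) stop("empty bootstrap distribution")
  if (a$statistic != b$statistic) stop("distributions are for different statistics")
  n <- min(length(a$draws), length(b$draws))
  if (length(a$draws) != length(b$draws)) {
    warning("unequal iteration counts; comparing the first ", n, " paired draws")
  }
  da <- a$draws[seq_len(n)]; db <- b$draws[seq_len(n)]
  prop <- mean(da > db)
  data.frame(statistic = a$statistic,
             group_a = a$group_label, group_b = b$group_label,
             mean_a = mean(a$draws), sd_a = stats::sd(a$draws),
             mean_b = mean(b$draws), sd_b = stats::sd(b$draws),
             prop_a_gt_b = prop,
             separated = prop >= 0.975 || prop <= 0.025,
             stringsAsFactors = FALSE)
}
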