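#' Mutagenesis screen site definitions
#'
#' The nine mutated sites of the combinatorial indicator library and their
#' allowed states (wild type plus one or two substitutions); the full
#' cross gives 1,728 genotypes.
#'
#' @return named list of level vectors, wild type (`"WT"`) first.
#' @export
screen_sites <- function() {
  list(Y31 = c("WT", "Q", "E"), Q34 = c("WT", "A"), Q98 = c("WT", "F"),
       A185 = c("WT", "N"), T254 = c("WT", "R"), K271 = c("WT", "F", "G"),
       H273 = c("WT", "E"), Q418 = c("WT", "S"), N499 = c("WT", "L", "V"))
}

#' All genotypes of the combinatorial screen
#'
#' @return data.frame with one factor column per site (WT reference
#'   level), 1,728 rows.
#' @export
screen_genotypes <- function() {
  sites <- screen_sites()
  g <- do.call(expand.grid, c(sites, stringsAsFactors = FALSE))
  for (s in names(sites)) g[[s]] <- factor(g[[s]], levels = sites[[s]])
  g
}

# Design matrix: one-hot non-reference site levels, plus (optionally) all
# products of level-pair dummies at distinct sites. Interaction columns
# are named "siteA.lvl:siteB.lvl".
screen_design <- function(geno, interactions = FALSE) {
  sites <- names(screen_sites())
  geno <- geno[sites]
  for (s in sites)
    if (!is.factor(geno[[s]]))
      geno[[s]] <- factor(geno[[s]], levels = screen_sites()[[s]])
  main <- stats::model.matrix(~., data = geno)
  colnames(main) <- sub("^\\(Intercept\\)$", "(Intercept)", colnames(main))
  if (!interactions) return(main)
  dum <- main[, -1L, drop = FALSE]
  site_of <- rep(sites, times = vapply(screen_sites(), length, 1L) - 1L)
  cols <- list()
  nm <- character(0)
  nd <- ncol(dum)
  for (i in seq_len(nd - 1L)) for (j in (i + 1L):nd) {
    if (site_of[i] == site_of[j]) next
    cols[[length(cols) + 1L]] <- dum[, i] * dum[, j]
    nm <- c(nm, paste(colnames(dum)[i], colnames(dum)[j], sep = ":"))
  }
  inter <- do.call(cbind, cols)
  colnames(inter) <- nm
  cbind(main, inter)
}

#' Simulate a combinatorial-mutagenesis screen table
#'
#' Generates per-well measurements from a known log-linear model: main
#' effects drawn `N(0, main_sd)` for every non-reference level, pairwise
#' interactions `N(0, int_sd)` on a random `int_frac` of site-level pairs,
#' and zero elsewhere. Poisson-family metrics are simulated as scaled
#' Poisson counts (`y = Pois(scale * mu) / scale`), Gaussian-log metrics
#' as `exp(eta) + N(0, noise_sd)`.
#'
#' @param n_genotypes genotypes to include (sampled without replacement
#'   from the 1,728; `NULL` means all).
#' @param reps replicate wells per genotype (kept unaveraged).
#' @param family `"poisson"` or `"gaussian_log"`.
#' @param main_sd,int_sd,int_frac effect-size model.
#' @param intercept model intercept (log scale).
#' @param scale Poisson photon scale (larger = less relative noise).
#' @param noise_sd Gaussian-family noise sd.
#' @param seed integer seed.
#' @return list: `table` (data.frame: site columns, plate, well, metric),
#'   `truth` (named beta vector incl. intercept), `metric` name.
#' @export
simulate_screen <- function(n_genotypes = NULL, reps = 4L,
                            family = c("poisson", "gaussian_log"),
                            main_sd = 0.3, int_sd = 0.2, int_frac = 0.1,
                            intercept = 0, scale = 50, noise_sd = 0.05,
                            seed = 1L) {
  family <- match.arg(family)
  with_seed(seed, {
    geno <- screen_genotypes()
    if (!is.null(n_genotypes))
      geno <- geno[sample(nrow(geno), n_genotypes), , drop = FALSE]
    x <- screen_design(geno, interactions = TRUE)
    nm <- colnames(x)
    beta <- stats::setNames(numeric(length(nm)), nm)
    beta["(Intercept)"] <- intercept
    is_int <- grepl(":", nm, fixed = TRUE)
    mains <- !is_int & nm != "(Intercept)"
    beta[mains] <- stats::rnorm(sum(mains), 0, main_sd)
    which_int <- which(is_int)
    active <- sample(which_int, round(int_frac * length(which_int)))
    beta[active] <- stats::rnorm(length(active), 0, int_sd)
    tab <- geno[rep(seq_len(nrow(geno)), each = reps), , drop = FALSE]
    eta <- rep(as.numeric(x %*% beta), each = reps)
    y <- if (family == "poisson") stats::rpois(length(eta), scale * exp(eta)) / scale
         else pmax(exp(eta) + stats::rnorm(length(eta), 0, noise_sd), 1e-6)
    tab$plate <- 1L + (seq_len(nrow(tab)) - 1L) %/% 96L
    tab$well <- seq_len(nrow(tab))
    tab$metric <- y
    rownames(tab) <- NULL
    list(table = tab, truth = beta, metric = "metric", family = family)
  })
}

#' Fit the categorical screen GLM
#'
#' Iteratively reweighted maximum-likelihood fit of a screen metric on the
#' 9 categorical sites (wild-type reference coding) with optional pairwise
#' epistatic interaction terms. The Poisson family with log link fits
#' F0-like and dF/F0-like metrics (point estimates are obtained through
#' `quasipoisson`, which shares the Poisson IRLS solution while accepting
#' continuous normalized responses); the Gaussian family with log link
#' fits rise/decay times. Negative metric values are clipped to 0
#' (Gaussian-log zeros are floored at a small epsilon with a warning).
#'
#' @param table screen data.frame: one column per site plus the metric.
#' @param metric metric column name.
#' @param family `"poisson"` or `"gaussian_log"`.
#' @param interactions include pairwise interaction terms?
#' @return list of class `screen_glm`: `coefficients`, `fit` (the `glm`
#'   object), `metric`, `family`, `interactions`, `converged`.
#' @export
fit_screen_glm <- function(table, metric = "metric",
                           family = c("poisson", "gaussian_log"),
                           interactions = FALSE) {
  family <- match.arg(family)
  y <- table[[metric]]
  if (is.null(y)) stopf("metric column '%s' not found", metric)
  y <- pmax(y, 0)
  if (family == "gaussian_log" && any(y == 0)) {
    warnf("flooring %d zero responses at 1e-6 for the log link", sum(y == 0))
    y <- pmax(y, 1e-6)
  }
  x <- screen_design(table, interactions = interactions)
  qr_x <- qr(x)
  if (qr_x$rank < ncol(x)) {
    aliased <- colnames(x)[qr_x$pivot[(qr_x$rank + 1L):ncol(x)]]
    stopf("rank-deficient design; aliased columns: %s",
          paste(aliased, collapse = ", "))
  }
  fam <- if (family == "poisson") stats::quasipoisson(link = "log")
         else stats::gaussian(link = "log")
  fit <- suppressWarnings(stats::glm.fit(x, y, family = fam,
                                         mustart = pmax(y, 0.1),
                                         control = list(maxit = 100)))
  if (!fit$converged) warnf("GLM did not converge")
  structure(list(coefficients = stats::setNames(fit$coefficients,
                                                colnames(x)),
                 fit = fit, metric = metric, family = family,
                 interactions = interactions, converged = fit$converged),
            class = "screen_glm")
}

#' @export
predict.screen_glm <- function(object, newdata, ...) {
  x <- screen_design(newdata, interactions = object$interactions)
  exp(as.numeric(x %*% object$coefficients))
}

#' Case-resampling bootstrap confidence intervals for screen coefficients
#'
#' Refits the GLM on `n_boot` resamples of the rows (N drawn with
#' replacement out of N), giving percentile 2.5/97.5 intervals per
#' coefficient. A coefficient is significant when 0 lies outside its 95%
#' interval. Resamples that fail to fit are redrawn (count reported).
#'
#' @param table,metric,family,interactions as in [fit_screen_glm()].
#' @param n_boot bootstrap resamples (>= 100 recommended for reporting).
#' @param seed integer seed.
#' @return data.frame: term, estimate, ci_lo, ci_hi, significant; with
#'   attribute `n_refit`.
#' @export
bootstrap_cis <- function(table, metric = "metric",
                          family = c("poisson", "gaussian_log"),
                          interactions = FALSE, n_boot = 1000L, seed = 1L) {
  family <- match.arg(family)
  base <- fit_screen_glm(table, metric, family, interactions)
  n <- nrow(table)
  n_refit <- 0L
  with_seed(seed, {
    draws <- matrix(NA_real_, n_boot, length(base$coefficients))
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        co <- tryCatch(
          suppressWarnings(
            fit_screen_glm(table[idx, , drop = FALSE], metric, family,
                           interactions)$coefficients),
          error = function(e) NULL)
        if (!is.null(co) && all(is.finite(co))) break
        n_refit <- n_refit + 1L
        if (n_refit > 10L * n_boot) stopf("bootstrap refits keep failing")
      }
      draws[b, ] <- co
    }
    ci <- apply(draws, 2L, stats::quantile, probs = c(0.025, 0.975))
    out <- data.frame(term = names(base$coefficients),
                      estimate = as.numeric(base$coefficients),
                      ci_lo = ci[1L, ], ci_hi = ci[2L, ])
    out$significant <- out$ci_lo > 0 | out$ci_hi < 0
    rownames(out) <- NULL
    attr(out, "n_refit") <- n_refit
    out
  })
}

#' Cross-validated variance explained of the screen GLM
#'
#' Genotype-stratified k-fold cross-validation (all replicates of a
#' genotype stay in the same fold); out-of-fold predictions are pooled and
#' scored as `1 - SSE/SST` against the pooled held-out mean. Folds whose
#' fit fails are skipped with a warning.
#'
#' @param table,metric,family,interactions as in [fit_screen_glm()].
#' @param k folds.
#' @param seed integer seed for the genotype-to-fold assignment.
#' @return scalar fraction of variance explained.
#' @export
cv_variance_explained <- function(table, metric = "metric",
                                  family = c("poisson", "gaussian_log"),
                                  interactions = FALSE, k = 5L, seed = 1L) {
  family <- match.arg(family)
  sites <- names(screen_sites())
  gid <- do.call(paste, c(lapply(sites, function(s) as.character(table[[s]])),
                          sep = "|"))
  ug <- unique(gid)
  with_seed(seed, {
    fold_of <- stats::setNames(sample(rep(seq_len(k), length.out = length(ug))),
                               ug)
  })
  pred <- obs <- list()
  for (f in seq_len(k)) {
    hold <- fold_of[gid] == f
    fit <- tryCatch(
      suppressWarnings(fit_screen_glm(table[!hold, , drop = FALSE], metric,
                                      family, interactions)),
      error = function(e) NULL)
    if (is.null(fit)) {
      warnf("fold %d failed to fit; skipped", f)
      next
    }
    pred[[length(pred) + 1L]] <- predict(fit, table[hold, , drop = FALSE])
    obs[[length(obs) + 1L]] <- pmax(table[hold, ][[metric]], 0)
  }
  y <- unlist(obs)
  yh <- unlist(pred)
  1 - sum((y - yh)^2) / sum((y - mean(y))^2)
}

#' Minimum inter-atom distances between mutated sites
#'
#' @param coords data.frame: site, atom, x, y, z (one row per atom).
#' @return data.frame: site_a, site_b, distance (closest atom pair).
#' @export
site_pair_distances <- function(coords) {
  need <- c("site", "x", "y", "z")
  if (!all(need %in% names(coords))) stopf("coords needs site, x, y, z")
  sites <- unique(as.character(coords$site))
  out <- list()
  for (i in seq_along(sites)[-length(sites)]) for (j in (i + 1L):length(sites)) {
    a <- coords[coords$site == sites[i], c("x", "y", "z"), drop = FALSE]
    b <- coords[coords$site == sites[j], c("x", "y", "z"), drop = FALSE]
    d2 <- outer(rowSums(a^2), rowSums(b^2), "+") -
      2 * as.matrix(a) %*% t(as.matrix(b))
    out[[length(out) + 1L]] <- data.frame(site_a = sites[i],
                                          site_b = sites[j],
                                          distance = sqrt(max(0, min(d2))))
  }
  do.call(rbind, out)
}

#' Correlation between epistatic interaction magnitude and residue distance
#'
#' Pearson correlation between `|interaction coefficient|` and the minimum
#' inter-atom Euclidean distance of the corresponding site pair (local
#' structural contacts are expected to interact more, giving a negative
#' correlation). Pairs whose sites lack coordinates are excluded with a
#' message.
#'
#' @param fit a `screen_glm` fitted with `interactions = TRUE` (or a
#'   coefficient table from [bootstrap_cis()]).
#' @param coords atom-coordinate data.frame (see
#'   [site_pair_distances()]).
#' @return list: `r`, `p`, `n_terms`, `data` (term, site pair, |coef|,
#'   distance).
#' @export
interaction_distance_correlation <- function(fit, coords) {
  co <- if (inherits(fit, "screen_glm")) fit$coefficients
        else stats::setNames(fit$estimate, fit$term)
  terms <- names(co)[grepl(":", names(co), fixed = TRUE)]
  if (!length(terms)) stopf("fit has no interaction terms")
  dists <- site_pair_distances(coords)
  key <- paste(pmin(dists$site_a, dists$site_b),
               pmax(dists$site_a, dists$site_b))
  site_of_term <- function(half) sub("^([A-Za-z]+[0-9]+).*$", "\\1", half)
  parts <- strsplit(terms, ":", fixed = TRUE)
  sa <- vapply(parts, function(p) site_of_term(p[1L]), character(1L))
  sb <- vapply(parts, function(p) site_of_term(p[2L]), character(1L))
  tk <- paste(pmin(sa, sb), pmax(sa, sb))
  d <- dists$distance[match(tk, key)]
  keep <- !is.na(d)
  if (!all(keep))
    message(sum(!keep), " interaction terms lack coordinates; excluded")
  ct <- stats::cor.test(abs(co[terms])[keep], d[keep], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n_terms = sum(keep),
       data = data.frame(term = terms[keep], site_a = sa[keep],
                         site_b = sb[keep],
                         magnitude = abs(co[terms])[keep],
                         distance = d[keep]))
}
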