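# Exponential random graph model for dyad-independent term sets:
# edges, nodefactor(attribute), nodematch(attribute). For these terms the
# likelihood factorises over unordered dyads, so the MLE is computed
# exactly by Newton-Raphson on a collapsed dyad-pattern design (one row
# per distinct change-statistic vector), and the log-normalizer
# log(kappa) = sum over dyads of log(1 + exp(theta . delta)) is available
# in closed form. An MCMC maximum-likelihood path (Geyer-Thompson) over a
# tie-flip Metropolis sampler lives in mcmc.R.

#' Specify an ERGM term set
#'
#' Supported terms are dyad-independent: `edges` (edge count),
#' `nodefactor` (number of edge endpoints at each non-base level of a node
#' attribute — the attribute's main effect on degree), and `nodematch`
#' (number of edges whose endpoints share the attribute value — homophily).
#'
#' @param terms ordered subset of `c("edges", "nodefactor", "nodematch")`,
#'   no duplicates.
#' @param attribute node attribute name used by nodefactor/nodematch.
#' @param base_level attribute level absorbed into the baseline for
#'   nodefactor (default `"low"`).
#' @return object of class `ergm_spec`.
#' @export
#' @examples
#' ergm_spec()                      # edges + nodefactor + nodematch
#' ergm_spec("edges")               # the zero (control) model
ergm_spec <- function(terms = c("edges", "nodefactor", "nodematch"),
                      attribute = "burnout", base_level = "low") {
  allowed <- c("edges", "nodefactor", "nodematch")
  if (!length(terms) || !all(terms %in% allowed))
    stop("terms must be a non-empty subset of: ", paste(allowed, collapse = ", "))
  if (anyDuplicated(terms))
    stop("duplicate terms")
  structure(list(terms = terms, attribute = attribute, base_level = base_level),
            class = "ergm_spec")
}

ergm_levels <- function(status, spec) {
  lev <- sort(unique(as.character(status)))
  if (all(c("low", "high") %in% lev) && length(lev) == 2) lev <- c("low", "high")
  if (any(c("nodefactor", "nodematch") %in% spec$terms)) {
    if (is.null(status))
      stop("node attribute '", spec$attribute, "' missing from network")
    if ("nodefactor" %in% spec$terms && !(spec$base_level %in% lev))
      stop("base level '", spec$base_level, "' not among attribute levels")
  }
  lev
}

term_names <- function(spec, levels) {
  nm <- character()
  for (t in spec$terms) {
    nm <- c(nm, switch(t,
      edges = "edges",
      nodefactor = paste0("nodefactor.", spec$attribute, ".",
                          setdiff(levels, spec$base_level)),
      nodematch = paste0("nodematch.", spec$attribute)))
  }
  nm
}

#' Change statistics for one dyad
#'
#' The change in each sufficient statistic caused by adding the edge
#' (i, j), as a function of the two endpoints' attribute values only
#' (dyad independence): 1 for `edges`; the number of endpoints at each
#' non-base level for `nodefactor`; the indicator of equal values for
#' `nodematch`.
#'
#' @param status_i,status_j attribute values of the endpoints.
#' @param spec an [ergm_spec()].
#' @param levels attribute level set (defaults to the statuses seen).
#' @return named numeric vector, one entry per model statistic.
#' @export
#' @examples
#' change_statistics("high", "high")  # c(edges = 1, nodefactor = 2, match = 1)
change_statistics <- function(status_i, status_j,
                              spec = ergm_spec(),
                              levels = sort(unique(c(status_i, status_j, "low")))) {
  out <- numeric()
  for (t in spec$terms) {
    out <- c(out, switch(t,
      edges = 1,
      nodefactor = vapply(setdiff(levels, spec$base_level), function(l)
        sum(c(status_i, status_j) == l), 0),
      nodematch = as.numeric(status_i == status_j)))
  }
  names(out) <- term_names(spec, levels)
  out
}

# Collapse all N(N-1)/2 dyads into distinct attribute-pair patterns with
# their change-statistic vectors, dyad counts, and observed edge counts.
dyad_pattern_design <- function(g, spec) {
  lev <- ergm_levels(g$status, spec)
  status <- if (is.null(g$status)) rep("", g$n) else as.character(g$status)
  sl <- if (is.null(g$status)) "" else lev
  counts <- vapply(sl, function(l) sum(status == l), 0)
  pairs <- list(); m <- numeric(); labels <- character()
  for (a in seq_along(sl)) for (b in a:length(sl)) {
    la <- sl[a]; lb <- sl[b]
    cnt <- if (a == b) counts[a] * (counts[a] - 1) / 2 else counts[a] * counts[b]
    if (cnt > 0) {
      pairs[[length(pairs) + 1]] <- c(la, lb)
      m <- c(m, cnt)
      labels <- c(labels, paste(la, lb, sep = "--"))
    }
  }
  X <- do.call(rbind, lapply(pairs, function(p)
    change_statistics(p[1], p[2], spec, levels = lev)))
  rownames(X) <- labels
  key <- vapply(pairs, paste, "", collapse = "--")
  y <- setNames(numeric(length(key)), key)
  if (nrow(g$edges)) {
    si <- status[g$edges[, 1]]; sj <- status[g$edges[, 2]]
    # pattern keys use `sl` order, not lexicographic order of the labels
    ia <- match(si, sl); ib <- match(sj, sl)
    ek <- ifelse(ia <= ib, paste(si, sj, sep = "--"), paste(sj, si, sep = "--"))
    tt <- base::table(ek)
    y[names(tt)] <- as.numeric(tt)
  }
  list(X = X, m = m, y = unname(y), patterns = labels, levels = lev)
}

#' Sufficient statistics of a network under an ERGM specification
#'
#' @param g a `burnout_network`.
#' @param spec an [ergm_spec()].
#' @return named numeric vector: edge count, nodefactor endpoint counts,
#'   nodematch count, per the spec's term order.
#' @export
#' @examples
#' # triangle on statuses (high, high, low): edges 3, nodefactor 4, match 1
sufficient_statistics <- function(g, spec = ergm_spec()) {
  lev <- ergm_levels(g$status, spec)
  si <- g$status[g$edges[, 1]]; sj <- g$status[g$edges[, 2]]
  out <- numeric()
  for (t in spec$terms) {
    out <- c(out, switch(t,
      edges = nrow(g$edges),
      nodefactor = vapply(setdiff(lev, spec$base_level), function(l)
        sum(si == l) + sum(sj == l), 0),
      nodematch = sum(si == sj)))
  }
  names(out) <- term_names(spec, lev)
  out
}

new_ergm_fit <- function(coef, se, loglik, log_normalizer, D, n_nodes, spec,
                         method, suff, attr_levels = NULL, converged = TRUE,
                         diagnostic = NULL, fingerprint = NULL,
                         iterations = NA_integer_) {
  k <- length(coef)
  z <- coef / se
  structure(
    list(coefficients = coef, se = se, z = z,
         p_value = 2 * stats::pnorm(-abs(z)),
         loglik = loglik, log_normalizer = log_normalizer,
         aic = 2 * k - 2 * loglik, bic = k * log(D) - 2 * loglik,
         dyads = D, n_nodes = n_nodes, spec = spec, method = method,
         suff_stats = suff, attr_levels = attr_levels,
         converged = converged, diagnostic = diagnostic,
         fingerprint = fingerprint, iterations = iterations),
    class = "ergm_fit"
  )
}

network_fingerprint <- function(g) {
  paste(g$n, nrow(g$edges), sum(g$edges),
        paste(sort(base::table(g$status)), collapse = ","), sep = "|")
}

#' Exact maximum-likelihood ERGM fit for dyad-independent terms
#'
#' For dyad-independent term sets the ERGM likelihood is a product of
#' Bernoulli dyad likelihoods, so the MLE is found exactly by
#' Newton-Raphson (iteratively reweighted least squares) on the collapsed
#' dyad-pattern design. Standard errors come from the inverse observed
#' Fisher information; p-values are two-sided normal (Wald). AIC = 2k - 2l
#' and BIC = k ln(D) - 2l with D = N(N-1)/2 the dyad count.
#'
#' @param g a `burnout_network` with burnout status on the nodes (unless
#'   the spec is edges-only).
#' @param spec an [ergm_spec()] with dyad-independent terms.
#' @param tol Newton convergence tolerance on the step max-norm.
#' @param max_iter maximum Newton iterations.
#' @return object of class `ergm_fit`.
#' @export
#' @examples
#' ## edges-only fit recovers logit(density)
fit_exact <- function(g, spec = ergm_spec(), tol = 1e-12, max_iter = 100) {
  des <- dyad_pattern_design(g, spec)
  X <- des$X; m <- des$m; y <- des$y
  k <- ncol(X)
  D <- g$n * (g$n - 1) / 2
  degenerate <- des$patterns[y == 0 | y == m]
  theta <- rep(0, k)
  dens <- sum(y) / sum(m)
  if ("edges" %in% spec$terms && dens > 0 && dens < 1)
    theta[which(colnames(X) == "edges")] <- stats::qlogis(dens)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% theta)
    p <- stats::plogis(eta)
    w <- m * p * (1 - p)
    grad <- drop(crossprod(X, y - m * p))
    H <- crossprod(X, X * w)
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    theta <- theta + step
    if (max(abs(step)) < tol) { converged <- TRUE; break }
  }
  if (any(!is.finite(theta)) || max(abs(theta)) > 15) converged <- FALSE
  eta <- drop(X %*% theta)
  p <- stats::plogis(eta)
  ll <- sum(y * eta - m * log1p(exp(eta)))
  log_kappa <- sum(m * log1p(exp(eta)))
  H <- crossprod(X, X * (m * p * (1 - p)))
  se <- tryCatch(sqrt(diag(solve(H))), error = function(e) rep(NA_real_, k))
  coef <- setNames(drop(theta), colnames(X))
  diagnostic <- if (!converged)
    paste0("non-converged exact fit",
           if (length(degenerate))
             paste0("; separation: pattern(s) with all or no edges: ",
                    paste(degenerate, collapse = ", ")))
  fit <- new_ergm_fit(coef, setNames(se, colnames(X)), ll, log_kappa, D,
                      g$n, spec, "exact_dyad", sufficient_statistics(g, spec),
                      attr_levels = des$levels,
                      converged = converged, diagnostic = diagnostic,
                      fingerprint = network_fingerprint(g))
  if (!converged)
    warning("fit_exact did not converge: ", diagnostic)
  fit
}

#' @export
print.ergm_fit <- function(x, ...) {
  cat(sprintf("ERGM fit (%s)%s: %d nodes, %g dyads\n",
              x$method, if (x$converged) "" else " [NOT CONVERGED]",
              x$n_nodes, x$dyads))
  fmt_p <- function(p) ifelse(p < 1e-4, "<1e-04", sprintf("%.4f", p))
  tab <- data.frame(
    `Estimated value (Std. Error)` =
      sprintf("%.2f (%.2f)", x$coefficients, x$se),
    `Z-value` = sprintf("%.2f", x$z),
    `p-Value` = fmt_p(x$p_value),
    check.names = FALSE, row.names = names(x$coefficients)
  )
  print(tab)
  cat(sprintf("AIC: %.0f   BIC: %.0f   logLik: %.1f\n", x$aic, x$bic, x$loglik))
  if (!is.null(x$diagnostic)) cat("diagnostic:", x$diagnostic, "\n")
  invisible(x)
}

#' Simulate a network from a dyad-independent ERGM
#'
#' Each unordered dyad is an independent Bernoulli draw with probability
#' `plogis(theta . delta(i, j))`, where delta is the dyad's
#' change-statistic vector.
#'
#' @param theta coefficient vector (spec term order).
#' @param status per-node attribute values.
#' @param spec an [ergm_spec()].
#' @param seed integer RNG seed.
#' @param ids optional node ids.
#' @return a `burnout_network`.
#' @export
simulate_network <- function(theta, status, spec = ergm_spec(), seed = 1L,
                             ids = NULL) {
  n <- length(status)
  if (is.null(ids)) ids <- sprintf("N%05d", seq_len(n))
  lev <- ergm_levels(status, spec)
  set.seed(as.integer(seed))
  # probability per attribute-pair pattern
  pat <- expand.grid(a = seq_along(lev), b = seq_along(lev))
  pat <- pat[pat$a <= pat$b, ]
  pmat <- matrix(NA_real_, length(lev), length(lev))
  for (r in seq_len(nrow(pat))) {
    d <- change_statistics(lev[pat$a[r]], lev[pat$b[r]], spec, levels = lev)
    if (length(d) != length(theta))
      stop("theta has length ", length(theta), " but spec has ",
           length(d), " statistics")
    pmat[pat$a[r], pat$b[r]] <- pmat[pat$b[r], pat$a[r]] <-
      stats::plogis(sum(theta * d))
  }
  code <- match(status, lev)
  i <- rep.int(seq_len(n - 1L), (n - 1L):1L)
  j <- sequence((n - 1L):1L) + i
  p <- pmat[cbind(code[i], code[j])]
  keep <- stats::runif(length(p)) < p
  new_network(ids, status, cbind(i[keep], j[keep]), n)
}

#' Compare the zero (edges-only) and node-attribute ERGMs
#'
#' Reports both models' AIC and BIC, selects the lower on each criterion,
#' and flags disagreement between criteria or exact ties. Both fits must
#' come from the same network, and one term set must nest the other.
#'
#' @param fit_zero,fit_attr `ergm_fit` objects on the same network with
#'   nested term sets.
#' @return object of class `ergm_comparison`: list with a `criteria`
#'   data.frame, the selected model per criterion, the overall `selected`
#'   model (`NA` on disagreement), and `tie`/`disagreement` flags.
#' @export
compare_models <- function(fit_zero, fit_attr) {
  if (!identical(fit_zero$fingerprint, fit_attr$fingerprint))
    stop("fits come from different networks")
  t0 <- fit_zero$spec$terms; t1 <- fit_attr$spec$terms
  if (!(all(t0 %in% t1) || all(t1 %in% t0)))
    stop("term sets are not nested")
  criteria <- data.frame(
    model = c("zero", "node_attribute"),
    k = c(length(fit_zero$coefficients), length(fit_attr$coefficients)),
    loglik = c(fit_zero$loglik, fit_attr$loglik),
    aic = c(fit_zero$aic, fit_attr$aic),
    bic = c(fit_zero$bic, fit_attr$bic),
    stringsAsFactors = FALSE
  )
  tie <- fit_zero$aic == fit_attr$aic && fit_zero$bic == fit_attr$bic
  sel_aic <- criteria$model[which.min(criteria$aic)]
  sel_bic <- criteria$model[which.min(criteria$bic)]
  disagreement <- !tie && sel_aic != sel_bic
  structure(
    list(criteria = criteria, selected_aic = sel_aic, selected_bic = sel_bic,
         selected = if (tie || disagreement) NA_character_ else sel_aic,
         tie = tie, disagreement = disagreement),
    class = "ergm_comparison"
  )
}

#' @export
print.ergm_comparison <- function(x, ...) {
  print(x$criteria)
  if (x$tie) cat("models tie on both criteria\n")
  else if (x$disagreement)
    cat("criteria disagree: AIC selects", x$selected_aic,
        "; BIC selects", x$selected_bic, "\n")
  else cat("selected:", x$selected, "(lower AIC and BIC)\n")
  invisible(x)
}

#' Predicted edge probability for a status pair
#'
#' `plogis(theta . delta(status_i, status_j))` under a fitted
#' dyad-independent ERGM.
#'
#' @param fit an `ergm_fit`.
#' @param status_i,status_j burnout statuses of the two nodes.
#' @return probability of an edge between such a pair.
#' @export
#' @examples
#' ## at theta = (-4.65, -0.14, 0.09): p(low, low) = plogis(-4.56) ~ 0.0104
predicted_edge_probability <- function(fit, status_i, status_j) {
  lev <- fit$attr_levels
  if (is.null(lev) || !length(lev))
    lev <- ergm_levels(unique(c(status_i, status_j, fit$spec$base_level)), fit$spec)
  if (!all(c(status_i, status_j) %in% c(lev, "")))
    stop("status value not among the fitted attribute levels")
  d <- change_statistics(status_i, status_j, fit$spec, levels = lev)
  if (length(d) != length(fit$coefficients))
    stop("status levels inconsistent with the fitted model")
  unname(stats::plogis(sum(fit$coefficients * d)))
}

#' Write an ERGM fit as JSON and as a report-style text table
#'
#' @param fit an `ergm_fit`.
#' @param json_path,table_path output paths (either may be `NULL`).
#' @export
write_ergm_fit <- function(fit, json_path = NULL, table_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(method = fit$method, terms = names(fit$coefficients),
           coefficients = as.list(fit$coefficients), se = as.list(fit$se),
           z = as.list(fit$z), p_value = as.list(fit$p_value),
           loglik = fit$loglik, aic = fit$aic,
           bic = fit$bic, dyads = fit$dyads, n_nodes = fit$n_nodes,
           converged = fit$converged),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(table_path)) {
    con <- file(table_path, "w")
    sink(con); print(fit); sink()
    close(con)
  }
  invisible(fit)
}
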