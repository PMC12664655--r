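#' @title Concentration-response modelling
#' @name doseresp
#' @description Per-gene and per-pathway response profiles across a dose
#'   series, four-parameter logistic (4PL) fitting on the log10-dose axis
#'   and EC50 extraction. The vehicle (zero dose) anchors the response
#'   definition (log2 fold change vs vehicle) and never enters the log-dose
#'   fit.
NULL

#' Evaluate the 4PL model
#'
#' `y(x) = lower + (upper - lower) / (1 + (ec50/x)^h)`; the sign of the
#' Hill coefficient `h` selects rising (`h > 0`) or falling curves, and
#' `y(ec50) = (lower + upper)/2` exactly.
#'
#' @param x Dose(s), positive.
#' @param lower,upper Asymptotes.
#' @param h Hill coefficient.
#' @param ec50 Half-maximal dose.
#' @return Response value(s).
#' @export
fourpl <- function(x, lower, upper, h, ec50) {
  lower + (upper - lower) / (1 + (ec50 / x)^h)
}

#' Fit a four-parameter logistic curve
#'
#' Nonlinear least squares on the log10-dose axis, initialised from a grid
#' over Hill coefficients `{+-0.5, +-1, +-2}` and EC50 candidates at dose
#' quantiles; the best starts are refined with Levenberg-Marquardt and the
#' final RSS never exceeds the best grid start's. Flat responses (range
#' below `flat_tol`) are reported unconverged with an undefined EC50 rather
#' than extrapolated.
#'
#' @param doses Positive dose vector (>= 4 distinct values).
#' @param responses Response per dose (log2 fold change for genes, NES for
#'   pathways).
#' @param h_bounds Bounds on the Hill coefficient.
#' @param ec50_bounds Bounds on EC50; default `[min dose / 100, max dose x
#'   100]`.
#' @param flat_tol Response range below which the curve is declared flat.
#' @return A `fourpl_fit`: `lower`, `upper`, `hill`, `ec50`, `rss`,
#'   `converged`, `ec50_in_range`.
#' @export
fit_4pl <- function(doses, responses, h_bounds = c(-10, 10),
                    ec50_bounds = NULL, flat_tol = 1e-8) {
  ok <- is.finite(doses) & is.finite(responses)
  doses <- doses[ok]; responses <- responses[ok]
  if (length(unique(doses)) < 4)
    stop("4PL fitting needs at least 4 distinct positive doses")
  if (any(doses <= 0)) stop("doses must be strictly positive")
  out <- list(lower = NA_real_, upper = NA_real_, hill = NA_real_,
              ec50 = NA_real_, rss = NA_real_, converged = FALSE,
              ec50_in_range = FALSE)
  if (diff(range(responses)) < flat_tol) {
    out$rss <- sum((responses - mean(responses))^2)
    return(structure(out, class = "fourpl_fit"))
  }
  if (is.null(ec50_bounds)) ec50_bounds <- c(min(doses) / 100, max(doses) * 100)
  lx <- log10(doses)
  model_rss <- function(p) {
    pred <- p[1] + (p[2] - p[1]) / (1 + 10^(p[3] * (p[4] - lx)))
    sum((pred - responses)^2)
  }
  # grid of starts: h sign/steepness x EC50 at dose quantiles
  qs <- quantile(doses, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE)
  lo0 <- responses[which.min(lx)]; hi0 <- responses[which.max(lx)]
  starts <- list()
  for (h0 in c(-2, -1, -0.5, 0.5, 1, 2)) for (e0 in qs)
    starts[[length(starts) + 1]] <- c(lo0, hi0, h0, log10(e0))
  rss0 <- vapply(starts, model_rss, numeric(1))
  best_start_rss <- min(rss0)
  lower_b <- c(-Inf, -Inf, h_bounds[1], log10(ec50_bounds[1]))
  upper_b <- c(Inf, Inf, h_bounds[2], log10(ec50_bounds[2]))
  best <- NULL; best_rss <- Inf
  # refine the most promising starts; some starts yield singular
  # gradients (the model is flat in some directions there), so keep
  # trying until a couple of refinements succeed
  n_ok <- 0
  for (i in order(rss0)) {
    if (n_ok >= 3) break
    p0 <- starts[[i]]
    fit <- tryCatch(minpack.lm::nlsLM(
      responses ~ A + (B - A) / (1 + 10^(H * (LE - lx))),
      start = list(A = p0[1], B = p0[2], H = p0[3], LE = p0[4]),
      lower = lower_b, upper = upper_b,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    n_ok <- n_ok + 1
    p <- coef(fit)
    r <- model_rss(p)
    if (r < best_rss) { best_rss <- r; best <- p }
  }
  if (is.null(best) || best_rss > best_start_rss) {
    # fall back to the best grid start if refinement failed or regressed
    best <- starts[[which.min(rss0)]]
    best_rss <- best_start_rss
    out$converged <- FALSE
  } else out$converged <- TRUE
  # the 4PL is invariant under (lower, upper, h) -> (upper, lower, -h);
  # report the canonical orientation with upper >= lower
  if (best[1] > best[2]) {
    best[1:2] <- best[2:1]
    best[3] <- -best[3]
  }
  out$lower <- unname(best[1]); out$upper <- unname(best[2])
  out$hill <- unname(best[3]); out$ec50 <- unname(10^best[4])
  out$rss <- best_rss
  out$ec50_in_range <- out$ec50 >= min(doses) && out$ec50 <= max(doses)
  structure(out, class = "fourpl_fit")
}

#' @export
print.fourpl_fit <- function(x, ...) {
  cat(sprintf(
    "4PL fit: lower=%.3g upper=%.3g hill=%.3g ec50=%.4g (in range: %s) rss=%.3g converged=%s\n",
    x$lower, x$upper, x$hill, x$ec50, x$ec50_in_range, x$rss, x$converged))
  invisible(x)
}

compound_doses <- function(screen, compound) {
  md <- screen$metadata
  doses <- sort(unique(md$concentration[md$treatment == compound &
                                          md$concentration > 0]))
  if (length(doses) < 4)
    stop(sprintf(paste0("compound '%s' has %d positive concentration(s); ",
                        ">= 4 are needed for dose-response modelling"),
                 compound, length(doses)))
  doses
}

#' Per-gene dose-response profiles
#'
#' For each concentration of a compound, runs the chosen DE engine against
#' the vehicle controls and records each gene's log2 fold change, giving
#' one response series per gene.
#'
#' @param screen A filtered `Screen`.
#' @param compound Treatment name present at >= 4 concentrations.
#' @param engine DE engine name.
#' @param control_label Vehicle treatment name.
#' @return A `dose_profile`: long `data.frame` (`gene_id`, `dose`,
#'   `response`, `stat`, `pvalue`) plus attribute `doses`.
#' @export
gene_response_profile <- function(screen, compound, engine = "nbql",
                                  control_label = "DMSO") {
  md <- screen$metadata
  doses <- compound_doses(screen, compound)
  ctrl <- control_wells(screen, control_label)
  if (length(ctrl) < 2) stop("missing controls: need >= 2 vehicle wells")
  rows <- lapply(doses, function(d) {
    tw <- md$barcode[md$treatment == compound & md$concentration == d]
    res <- de_run(engine, screen, de_design(tw, ctrl))
    data.frame(gene_id = res$gene_id, dose = d, response = res$log2fc,
               stat = res$stat, pvalue = res$pvalue)
  })
  out <- do.call(rbind, rows)
  attr(out, "doses") <- doses
  attr(out, "compound") <- compound
  class(out) <- c("dose_profile", "data.frame")
  out
}

#' Fit 4PL curves to every gene of a dose profile
#'
#' @param profile A [gene_response_profile()] result.
#' @param genes Optional subset of gene ids.
#' @param ... Passed to [fit_4pl()].
#' @return `data.frame`: one row per gene with the `fourpl_fit` fields.
#' @export
fit_dose_profiles <- function(profile, genes = NULL, ...) {
  ids <- unique(profile$gene_id)
  if (!is.null(genes)) ids <- intersect(ids, genes)
  rows <- lapply(ids, function(g) {
    sub <- profile[profile$gene_id == g, ]
    ft <- fit_4pl(sub$dose, sub$response, ...)
    data.frame(gene_id = g, lower = ft$lower, upper = ft$upper,
               hill = ft$hill, ec50 = ft$ec50, rss = ft$rss,
               converged = ft$converged, ec50_in_range = ft$ec50_in_range)
  })
  do.call(rbind, rows)
}

#' Pathway-level dose-response profiles
#'
#' For each concentration, runs the DE engine against vehicle and scores
#' each gene set, then fits a 4PL curve to the per-set response versus
#' dose. Two responses are available: the permutation `"nes"` (ranks genes
#' by the DE statistic; good for detecting at which dose a coherent
#' response *appears*, but it saturates once the shift is detectable, so
#' its half-max sits below the genes' half-maximal dose) and
#' `"mean_lfc"` (mean log2 fold change of the set genes, proportional to
#' the average gene response and therefore the right scale for potency /
#' EC50 estimation).
#'
#' @param screen A filtered `Screen`.
#' @param compound Treatment name present at >= 4 concentrations.
#' @param sets Named list of gene sets.
#' @param engine DE engine name.
#' @param control_label Vehicle treatment name.
#' @param response `"nes"` or `"mean_lfc"`.
#' @param n_perm,seed Permutation settings for the NES response.
#' @param ... Passed to [fit_4pl()].
#' @return List with `profile` (long `set`/`dose`/response data.frame) and
#'   `fits` (per-set 4PL table).
#' @export
pathway_response_profile <- function(screen, compound, sets, engine = "nbql",
                                     control_label = "DMSO",
                                     response = c("nes", "mean_lfc"),
                                     n_perm = 500L, seed = 1L, ...) {
  response <- match.arg(response)
  md <- screen$metadata
  doses <- compound_doses(screen, compound)
  ctrl <- control_wells(screen, control_label)
  gene_ids <- screen$counts$gene_ids
  usable <- vapply(sets, function(s) length(intersect(s, gene_ids)) >= 3,
                   logical(1))
  if (!any(usable)) stop("no gene set overlaps the screen's gene universe")
  sets <- sets[usable]
  rows <- lapply(doses, function(d) {
    tw <- md$barcode[md$treatment == compound & md$concentration == d]
    res <- de_run(engine, screen, de_design(tw, ctrl))
    if (response == "mean_lfc")
      return(do.call(rbind, lapply(names(sets), function(s) {
        idx <- res$gene_id %in% sets[[s]]
        data.frame(set = s, dose = d,
                   response = mean(res$log2fc[idx], na.rm = TRUE),
                   pvalue = NA_real_)
      })))
    ranked <- setNames(res$stat, res$gene_id)
    ranked <- ranked[!is.na(ranked)]
    do.call(rbind, lapply(names(sets), function(s) {
      gr <- gsea_preranked(ranked, sets[[s]], n_perm = n_perm, seed = seed)
      data.frame(set = s, dose = d, response = gr$nes, es = gr$es,
                 pvalue = gr$pvalue)
    }))
  })
  profile <- do.call(rbind, rows)
  names(profile)[names(profile) == "response"] <- response
  fits <- do.call(rbind, lapply(names(sets), function(s) {
    sub <- profile[profile$set == s & is.finite(profile[[response]]), ]
    if (length(unique(sub$dose)) < 4)
      return(data.frame(set = s, lower = NA, upper = NA, hill = NA,
                        ec50 = NA, rss = NA, converged = FALSE,
                        ec50_in_range = FALSE))
    ft <- fit_4pl(sub$dose, sub[[response]], ...)
    data.frame(set = s, lower = ft$lower, upper = ft$upper, hill = ft$hill,
               ec50 = ft$ec50, rss = ft$rss, converged = ft$converged,
               ec50_in_range = ft$ec50_in_range)
  }))
  list(profile = profile, fits = fits)
}
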