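## Dual-luciferase normalization and per-motif expression effects.
##
## Relative activity (in percent) rescales each construct's mean
## firefly/Renilla ratio between the negative (0%) and positive (100%)
## control ratios. The per-motif arithmetic reproduces the field convention
## of dividing an activity difference between two comparable constructs by
## the total number of motifs added and attributing it to the dominant added
## motif type; the regression model is the principled multi-construct
## alternative.

.CONTROL_TAGS <- c("NEGATIVE", "POSITIVE")

#' Relative luciferase activity per construct
#'
#' Per well, ratio = firefly / renilla. Per construct, activity percent =
#' 100 * (mean ratio - mean negative-control ratio) /
#' (mean positive-control ratio - mean negative-control ratio). The standard
#' error is propagated from the replicate variance of the experimental ratios
#' only (control means treated as fixed). When an \code{experiment} column is
#' present, normalization is per experiment and construct activities are
#' averaged across experiments (\code{perExperiment = FALSE} pools all wells
#' instead).
#'
#' @param wells data.frame with columns \code{construct_id}, \code{replicate},
#'   \code{firefly}, \code{renilla}, and optionally \code{experiment}.
#'   Controls are tagged \code{NEGATIVE} / \code{POSITIVE} in
#'   \code{construct_id}.
#' @param perExperiment Normalize within experiment before averaging.
#' @return data.frame: \code{construct_id}, \code{percent}, \code{se},
#'   \code{n}. NEGATIVE maps to 0 and POSITIVE to 100 by construction.
#' @export
relativeActivity <- function(wells, perExperiment = TRUE) {
  need <- c("construct_id", "firefly", "renilla")
  if (!all(need %in% colnames(wells)))
    stop("wells must have columns construct_id, firefly, renilla")
  if (any(wells$renilla <= 0)) stop("renilla counts must be positive")
  if (!any(wells$construct_id == "NEGATIVE") ||
      !any(wells$construct_id == "POSITIVE"))
    stop("wells must include NEGATIVE and POSITIVE control wells")

  one_batch <- function(w) {
    ratio <- w$firefly / w$renilla
    neg <- mean(ratio[w$construct_id == "NEGATIVE"])
    pos <- mean(ratio[w$construct_id == "POSITIVE"])
    if (pos <= neg)
      stop("degenerate normalization: positive-control ratio <= negative")
    span <- pos - neg
    ids <- unique(w$construct_id)
    do.call(rbind, lapply(ids, function(id) {
      r <- ratio[w$construct_id == id]
      pc <- 100 * (mean(r) - neg) / span
      se <- if (id %in% .CONTROL_TAGS || length(r) < 2L) 0 else
        100 * stats::sd(r) / sqrt(length(r)) / span
      data.frame(construct_id = id, percent = pc, se = se, n = length(r),
                 stringsAsFactors = FALSE)
    }))
  }

  if (perExperiment && "experiment" %in% colnames(wells) &&
      length(unique(wells$experiment)) > 1L) {
    per <- lapply(split(wells, wells$experiment), one_batch)
    ids <- unique(wells$construct_id)
    out <- do.call(rbind, lapply(ids, function(id) {
      pcs <- unlist(lapply(per, function(d) d$percent[d$construct_id == id]))
      ns <- sum(unlist(lapply(per, function(d) d$n[d$construct_id == id])))
      se <- if (id %in% .CONTROL_TAGS || length(pcs) < 2L) 0 else
        stats::sd(pcs) / sqrt(length(pcs))
      data.frame(construct_id = id, percent = mean(pcs), se = se, n = ns,
                 stringsAsFactors = FALSE)
    }))
  } else {
    out <- one_batch(wells)
  }
  rownames(out) <- NULL
  out
}

.motif_counts <- function(structure,
                          types = c("CA18", "CACA20", "CGCA20")) {
  vapply(types, function(t) sum(motifs(structure) == t), integer(1))
}

#' Per-motif expression effect from a pairwise construct comparison
#'
#' For two constructs of comparable composition where \code{structB} extends
#' \code{structA}: delta = activityA - activityB (the expression decrease),
#' per-motif effect = delta / total motifs added, attributed to the dominant
#' added motif type. Values are rounded to 2 decimals for reporting.
#'
#' @param actA,actB Relative activities (percent) of the smaller and larger
#'   construct.
#' @param structA,structB \linkS4class{AlleleStructure} objects;
#'   \code{structB} must not remove motifs present in \code{structA}.
#' @return List with \code{delta}, \code{perMotif}, \code{motifsAdded}
#'   (named per-type counts), \code{totalAdded}, \code{dominantMotif}.
#' @examples
#' a4 <- parseAlleleName("3xCACA20+CA18")
#' a10 <- parseAlleleName("7xCACA20+CA18+CACA20+CA18")
#' perMotifEffect(22.45, 19.69, a4, a10)
#' @export
perMotifEffect <- function(actA, actB, structA, structB) {
  ca <- .motif_counts(structA); cb <- .motif_counts(structB)
  added <- cb - ca
  if (any(added < 0))
    stop("structB does not extend structA (negative added counts: ",
         paste(names(added)[added < 0], collapse = ", "), ")")
  total <- sum(added)
  delta <- actA - actB
  per <- if (total == 0L) 0 else delta / total
  dominant <- if (total == 0L) NA_character_ else
    names(added)[which.max(added)]
  list(delta = round(delta, 2), perMotif = round(per, 2),
       motifsAdded = added, totalAdded = total, dominantMotif = dominant)
}

#' Linear per-motif expression model
#'
#' Least-squares fit of construct activity on per-type motif counts:
#' percent ~ intercept + beta_CA18 * nCA18 + beta_CACA20 * nCACA20 +
#' beta_CGCA20 * nCGCA20. Requires at least 4 constructs with distinct count
#' vectors and a full-rank design. Leave-one-out refits report coefficient
#' stability.
#'
#' @param activities data.frame with columns \code{construct_id},
#'   \code{percent}, and either a \code{structure} list-column of
#'   \linkS4class{AlleleStructure} or columns \code{nCA18}, \code{nCACA20},
#'   \code{nCGCA20}. Control rows (NEGATIVE/POSITIVE) are ignored.
#' @return List with \code{intercept}, \code{betas} (named), \code{fit} (the
#'   lm object), \code{residuals}, and \code{leaveOneOut} (matrix of
#'   coefficients from each refit; NA rows where a refit is rank-deficient).
#' @export
fitMotifModel <- function(activities) {
  act <- activities[!(activities$construct_id %in% .CONTROL_TAGS), ,
                    drop = FALSE]
  if (!all(c("nCA18", "nCACA20", "nCGCA20") %in% colnames(act))) {
    if (!"structure" %in% colnames(act))
      stop("activities needs per-type counts or a structure column")
    cnts <- t(vapply(act$structure, .motif_counts, integer(3)))
    act$nCA18 <- cnts[, "CA18"]; act$nCACA20 <- cnts[, "CACA20"]
    act$nCGCA20 <- cnts[, "CGCA20"]
  }
  X <- unique(act[, c("nCA18", "nCACA20", "nCGCA20")])
  if (nrow(X) < 4L)
    stop("need at least 4 constructs with distinct motif-count vectors")
  qrX <- qr(cbind(1, as.matrix(act[, c("nCA18", "nCACA20", "nCGCA20")])))
  if (qrX$rank < 4L)
    stop("rank-deficient design: motif counts are collinear across constructs")
  fit <- stats::lm(percent ~ nCA18 + nCACA20 + nCGCA20, data = act)
  cf <- stats::coef(fit)

  loo <- t(vapply(unique(act$construct_id), function(id) {
    sub <- act[act$construct_id != id, , drop = FALSE]
    q <- qr(cbind(1, as.matrix(sub[, c("nCA18", "nCACA20", "nCGCA20")])))
    if (q$rank < 4L) return(rep(NA_real_, 4L))
    stats::coef(stats::lm(percent ~ nCA18 + nCACA20 + nCGCA20, data = sub))
  }, numeric(4)))

  list(intercept = unname(cf[1]),
       betas = c(CA18 = unname(cf["nCA18"]), CACA20 = unname(cf["nCACA20"]),
                 CGCA20 = unname(cf["nCGCA20"])),
       fit = fit, residuals = stats::residuals(fit), leaveOneOut = loo)
}

#' One-way ANOVA with Tukey HSD post hoc test
#'
#' @param groups Named list of numeric replicate vectors (>= 2 groups, each
#'   with >= 2 replicates).
#' @param alpha Significance level (default 0.05).
#' @return List with \code{F}, \code{p}, \code{anova} (the aov fit),
#'   \code{tukey} (data.frame: comparison, diff, lwr, upr, pAdj,
#'   significant).
#' @export
oneWayAnovaTukey <- function(groups, alpha = 0.05) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop("every group needs at least 2 replicates")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("g", seq_along(groups))
  d <- data.frame(
    y = unlist(groups, use.names = FALSE),
    g = factor(rep(names(groups), vapply(groups, length, integer(1)))))
  fit <- stats::aov(y ~ g, data = d)
  s <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
  tukey <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      pAdj = tk[, "p adj"],
                      significant = tk[, "p adj"] < alpha,
                      stringsAsFactors = FALSE)
  rownames(tukey) <- NULL
  list(F = s[["F value"]][1], p = s[["Pr(>F)"]][1], anova = fit,
       tukey = tukey)
}
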