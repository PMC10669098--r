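#' Linear Cox risk model
#'
#' A gene-expression risk score `risk = sum(Exp(mRNA_x) * coef_x)`: a linear
#' combination of per-gene expression values with log-hazard coefficients,
#' no intercept. Coefficients are applied to the expression values as
#' supplied (the caller decides the normalization).
#'
#' @param genes character vector of gene symbols (unique).
#' @param coefs matching numeric coefficients.
#' @return object of class `risk_model`.
#' @export
risk_model <- function(genes, coefs) {
  genes <- toupper(as.character(genes))
  coefs <- as.numeric(coefs)
  if (length(genes) != length(coefs) || !length(genes)) {
    stop("genes and coefs must be non-empty and of equal length")
  }
  if (anyDuplicated(genes)) stop("duplicate genes in risk model")
  if (any(!is.finite(coefs))) stop("coefficients must be finite")
  structure(list(genes = genes, coefs = stats::setNames(coefs, genes)),
    class = "risk_model")
}

#' Read a risk model from a two-column TSV (gene, coef)
#' @param path TSV file with header columns `gene` and `coef`.
#' @return a [risk_model()].
#' @export
read_risk_model <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("gene", "coef") %in% names(df))) {
    stop("risk model file needs columns 'gene' and 'coef'")
  }
  risk_model(df$gene, df$coef)
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("linear risk model over %d gene(s):\n", length(x$genes)))
  cat(paste(sprintf("  %+0.3f x %s", x$coefs, x$genes), collapse = "\n"), "\n")
  invisible(x)
}

#' @export
coef.risk_model <- function(object, ...) object$coefs

#' Evaluate a risk model on expression data
#'
#' @param object a [risk_model()].
#' @param newdata a named numeric vector (one sample), a genes x samples
#'   matrix, or an `expr_matrix` (its normalized layer is used).
#' @param ... unused.
#' @return numeric vector of per-sample risk scores.
#' @export
predict.risk_model <- function(object, newdata, ...) {
  if (inherits(newdata, "expr_matrix")) newdata <- as.matrix(.norm_layer(newdata))
  one_sample <- is.vector(newdata)
  if (one_sample) newdata <- matrix(newdata, ncol = 1,
    dimnames = list(names(newdata), NULL))
  rn <- toupper(rownames(newdata))
  missing_genes <- setdiff(object$genes, rn)
  if (length(missing_genes)) {
    stop("expression lacks model gene(s): ", paste(missing_genes, collapse = ", "))
  }
  x <- newdata[match(object$genes, rn), , drop = FALSE]
  out <- as.vector(crossprod(x, object$coefs))
  if (!one_sample) names(out) <- colnames(newdata)
  out
}

#' Alias for evaluating a risk model
#' @inheritParams predict.risk_model
#' @param model a [risk_model()].
#' @param expr expression input, as in [predict.risk_model()].
#' @return numeric vector of risk scores.
#' @export
risk_score <- function(model, expr) predict(model, expr)

#' Univariate Cox screen over candidate genes
#'
#' Fits one proportional-hazards model per gene (partial likelihood, Efron
#' tie handling via `survival::coxph`) on the normalized bulk expression and
#' flags genes with Wald `p < p_max`. Genes whose fit fails or diverges are
#' dropped with a warning.
#'
#' @param bulk an `expr_matrix` with a normalized layer (genes x samples).
#' @param surv survival data.frame (`sample_id`, `time`, `event`) covering
#'   the bulk samples; at least 10 events required.
#' @param genes genes to screen (default: all bulk genes).
#' @param p_max selection threshold (default 0.05).
#' @param standardize z-score each gene across samples before fitting.
#' @return data.frame with `gene`, `coef`, `se`, `p`, `selected`.
#' @export
univariate_cox <- function(bulk, surv, genes = NULL, p_max = 0.05,
                           standardize = FALSE) {
  stopifnot(inherits(bulk, "expr_matrix"))
  surv <- validate_survival(surv)
  if (sum(surv$event) < 10) stop("need at least 10 events")
  if (is.null(genes)) genes <- rownames(bulk$counts)
  missing_genes <- setdiff(toupper(genes), rownames(bulk$counts))
  if (length(missing_genes)) {
    stop("gene(s) absent from bulk: ", paste(missing_genes, collapse = ", "))
  }
  x <- as.matrix(.norm_layer(bulk)[toupper(genes), surv$sample_id, drop = FALSE])
  if (standardize) {
    x <- t(scale(t(x)))
    x[is.nan(x)] <- 0
  }
  y <- survival::Surv(surv$time, surv$event)
  fits <- lapply(seq_len(nrow(x)), function(i) {
    fit <- tryCatch(
      survival::coxph(y ~ x[i, ], ties = "efron"),
      error = function(e) NULL, warning = function(w) NULL
    )
    if (is.null(fit) || !is.finite(stats::coef(fit)) ||
      abs(stats::coef(fit)) > 50) {
      return(NULL)
    }
    s <- summary(fit)$coefficients
    data.frame(gene = rownames(x)[i], coef = s[1, "coef"], se = s[1, "se(coef)"],
      p = s[1, "Pr(>|z|)"], stringsAsFactors = FALSE)
  })
  dropped <- sum(vapply(fits, is.null, logical(1)))
  if (dropped) warning(dropped, " gene(s) dropped (non-convergent or degenerate fit)")
  out <- do.call(rbind, fits)
  if (is.null(out)) stop("no gene produced a usable Cox fit")
  out$selected <- out$p < p_max
  rownames(out) <- NULL
  out
}

#' Split samples at the median risk score
#'
#' Scores strictly above the median go to the high group; scores at or below
#' the median go to the low group (documented tie rule).
#'
#' @param scores named numeric vector (>= 4 samples).
#' @return named character vector (`"high"`/`"low"`).
#' @export
stratify_median <- function(scores) {
  if (length(scores) < 4) stop("need at least 4 samples")
  med <- stats::median(scores)
  if (all(scores == scores[1])) stop("all scores identical: degenerate split")
  g <- ifelse(scores > med, "high", "low")
  if (!is.null(names(scores))) names(g) <- names(scores)
  g
}

#' Kaplan-Meier curves and log-rank comparison of risk groups
#'
#' @param surv survival data.frame (`sample_id`, `time`, `event`).
#' @param groups named character vector (sample_id -> group label) with
#'   exactly 2 non-empty groups.
#' @return list with `curves` — per group a data.frame (`time`, `surv`,
#'   `n_risk`, `n_event`) — and the two-group log-rank `p`.
#' @export
km_logrank <- function(surv, groups) {
  surv <- validate_survival(surv)
  g <- groups[surv$sample_id]
  if (anyNA(g)) stop("groups must cover every sample")
  if (length(unique(g)) != 2) stop("need exactly 2 non-empty groups")
  sf <- survival::survfit(survival::Surv(surv$time, surv$event) ~ g)
  strata <- rep(names(sf$strata), sf$strata)
  curves <- lapply(split(seq_along(sf$time), strata), function(idx) {
    data.frame(time = sf$time[idx], surv = sf$surv[idx],
      n_risk = sf$n.risk[idx], n_event = sf$n.event[idx])
  })
  names(curves) <- sub("^g=", "", names(curves))
  sd <- survival::survdiff(survival::Surv(surv$time, surv$event) ~ g)
  p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  list(curves = curves, p = p, chisq = sd$chisq)
}

#' Time-dependent ROC AUC for a risk score
#'
#' Cumulative-case / dynamic-control AUC at each horizon `t`: cases are
#' subjects with an event by `t`, controls those still under follow-up beyond
#' `t`, with inverse-probability-of-censoring weights from the Kaplan-Meier
#' estimate of the censoring distribution (Uno-type estimator). With no
#' censoring this reduces to the case/control Mann-Whitney statistic. Ties in
#' the score count 1/2.
#'
#' @param scores named numeric vector of risk scores (sample_id -> score).
#' @param surv survival data.frame (`sample_id`, `time`, `event`).
#' @param horizons numeric vector of evaluation times.
#' @return data.frame with `horizon`, `auc` (`NA` when a horizon has no case
#'   or no control or lies beyond follow-up), `n_case`, `n_control`.
#' @export
time_dependent_roc <- function(scores, surv, horizons) {
  surv <- validate_survival(surv)
  s <- scores[surv$sample_id]
  if (anyNA(s)) stop("scores must cover every sample")
  # KM of the censoring distribution; G(t-) via left-continuous lookup
  cens_fit <- survival::survfit(survival::Surv(surv$time, 1 - surv$event) ~ 1)
  G <- function(t) {
    # left-continuous censoring survival just before t
    vapply(t, function(tt) {
      idx <- cens_fit$time < tt
      if (!any(idx)) 1 else min(cens_fit$surv[idx])
    }, numeric(1))
  }
  out <- lapply(horizons, function(t) {
    if (t >= max(surv$time)) {
      return(data.frame(horizon = t, auc = NA_real_, n_case = NA_integer_,
        n_control = NA_integer_))
    }
    case <- surv$event == 1 & surv$time <= t
    control <- surv$time > t
    if (!any(case) || !any(control)) {
      return(data.frame(horizon = t, auc = NA_real_, n_case = sum(case),
        n_control = sum(control)))
    }
    w_case <- 1 / pmax(G(surv$time[case]), 1e-10)
    w_ctrl <- rep(1 / pmax(G(t + .Machine$double.eps), 1e-10), sum(control))
    sc <- s[case]
    sk <- s[control]
    conc <- outer(sc, sk, function(a, b) (a > b) + 0.5 * (a == b))
    w <- outer(w_case, w_ctrl)
    data.frame(horizon = t, auc = sum(conc * w) / sum(w),
      n_case = sum(case), n_control = sum(control))
  })
  do.call(rbind, out)
}
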