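#' Per-network counts of positive and negative associations
#'
#' @param networks list with elements `snow_free` and `snow_covered`, each
#'   a list of `association_network`s.
#' @return `data.frame` with columns `network_id`, `condition`, `n_pos`,
#'   `n_neg`.
#' @export
sign_count_records <- function(networks) {
  out <- list()
  for (cond in CONDITIONS) {
    for (net in networks[[cond]]) {
      out[[length(out) + 1L]] <- data.frame(
        network_id = paste(cond, net$t_fungal, net$t_bacterial, sep = "_"),
        condition = cond,
        n_pos = sum(net$edges$sign == "+"),
        n_neg = sum(net$edges$sign == "-"),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Binomial GLM of positive-association odds on snow cover
#'
#' Fits a logit-link binomial GLM with the per-network (positive, negative)
#' edge counts as the response and condition as the predictor, i.e. it
#' models whether an association is positive and how snow cover shifts the
#' odds. Networks without edges are excluded. Complete separation (all
#' edges of one condition sharing a sign) is flagged and handled by a
#' Haldane-Anscombe refit (0.5 added to every cell).
#'
#' @param records `data.frame` from [sign_count_records()].
#' @return list with `model` (the `glm` fit), `coefficients` (summary
#'   table), `fitted_odds` (named per-condition odds of a positive
#'   association), `p_condition` (Wald p for the condition effect), and
#'   `separation_corrected`.
#' @export
fit_sign_binomial <- function(records) {
  records <- records[records$n_pos + records$n_neg > 0L, , drop = FALSE]
  records$condition <- factor(records$condition, levels = CONDITIONS)
  if (nlevels(droplevels(records$condition)) < 2L) {
    stop("both conditions must be represented")
  }
  fit <- glm(cbind(n_pos, n_neg) ~ condition, family = binomial(),
             data = records)
  separated <- !fit$converged || any(abs(coef(fit)) > 15)
  if (separated) {
    warning("complete or quasi-complete separation; refitting with the ",
            "Haldane-Anscombe 0.5-count correction")
    rec2 <- records
    rec2$n_pos <- rec2$n_pos + 0.5
    rec2$n_neg <- rec2$n_neg + 0.5
    fit <- suppressWarnings(
      glm(cbind(n_pos, n_neg) ~ condition, family = binomial(), data = rec2))
  }
  sm <- summary(fit)$coefficients
  eta <- c(snow_free = unname(coef(fit)[1L]),
           snow_covered = unname(coef(fit)[1L] + coef(fit)[2L]))
  list(model = fit, coefficients = sm,
       fitted_odds = exp(eta),
       odds_ratio = exp(unname(coef(fit)[2L])),
       p_condition = sm[2L, "Pr(>|z|)"],
       separation_corrected = separated)
}

#' Per-network fb association counts by fungal phylum
#'
#' For every network, fungal-bacterial edges are grouped by the phylum
#' annotation of the fungal partner and counted, giving the response for
#' the Poisson frequency models. Every phylum present in any network of the
#' same filter pair appears in every row block (zero-filled), so condition
#' contrasts are well defined.
#'
#' @param networks list with elements `snow_free` and `snow_covered`.
#' @param taxonomy taxonomy `data.frame`.
#' @return `data.frame` with columns `t_fungal`, `t_bacterial`,
#'   `condition`, `phylum`, `n_fb`.
#' @export
phylum_freq_records <- function(networks, taxonomy) {
  phy <- setNames(taxonomy$phylum, taxonomy$asv_id)
  rows <- list()
  for (cond in CONDITIONS) {
    for (net in networks[[cond]]) {
      e <- net$edges[net$edges$type == "fb", , drop = FALSE]
      kin <- setNames(net$nodes$kingdom, net$nodes$id)
      fid <- ifelse(kin[e$a] == "fungi", e$a, e$b)
      ph <- phy[fid]
      ph[is.na(ph)] <- "unknown"
      tab <- table(ph)
      k <- length(tab)
      rows[[length(rows) + 1L]] <- data.frame(
        t_fungal = rep(net$t_fungal, k), t_bacterial = rep(net$t_bacterial, k),
        condition = rep(cond, k),
        phylum = if (k) names(tab) else character(0),
        n_fb = if (k) as.integer(tab) else integer(0),
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  # zero-fill phyla missing from one condition of the same filter pair
  out <- list()
  for (key in unique(paste(df$t_fungal, df$t_bacterial))) {
    sub <- df[paste(df$t_fungal, df$t_bacterial) == key, , drop = FALSE]
    full <- expand.grid(phylum = unique(sub$phylum), condition = CONDITIONS,
                        stringsAsFactors = FALSE)
    full$t_fungal <- sub$t_fungal[1L]
    full$t_bacterial <- sub$t_bacterial[1L]
    i <- match(paste(full$phylum, full$condition),
               paste(sub$phylum, sub$condition))
    full$n_fb <- ifelse(is.na(i), 0L, sub$n_fb[i])
    out[[key]] <- full[, c("t_fungal", "t_bacterial", "condition",
                           "phylum", "n_fb")]
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Stepwise AIC model selection
#'
#' Bidirectional stepping (R's `step`) from the main-effects model within a
#' hierarchical scope from the intercept-only model up to the full
#' interaction; stepping stops when no single term addition or removal
#' lowers the AIC.
#'
#' @param fit starting `glm` fit; its variables must be plain columns of
#'   the data (the model frame is reused when the stepping re-fits
#'   candidate models).
#' @param lower,upper formula bounds of the scope.
#' @return the selected `glm` fit (with the usual `anova` step trace).
#' @export
stepwise_aic <- function(fit, lower = ~1, upper = NULL) {
  # step() re-evaluates the fitting call in the calling frame, so pin the
  # data down via the model frame to stay independent of caller scoping
  env <- new.env(parent = environment(formula(fit)))
  env$.step_data <- fit$model
  fit$call$data <- quote(.step_data)
  attr(fit$terms, ".Environment") <- env
  environment(fit$formula) <- env
  env$.step_fit <- fit
  if (is.null(upper)) {
    eval(quote(step(.step_fit, direction = "both", trace = 0)), env)
  } else {
    env$.step_scope <- list(lower = lower, upper = upper)
    eval(quote(step(.step_fit, scope = .step_scope, direction = "both",
                    trace = 0)), env)
  }
}

#' Poisson GLM of fb association frequency by fungal phylum and snow cover
#'
#' Log-link Poisson model of the per-network fb association counts with
#' candidate terms phylum, condition and their interaction; the final model
#' is chosen by bidirectional stepwise AIC starting from the main-effects
#' model. Phyla with zero counts in both conditions are dropped (log-link
#' degeneracy). Typically applied per filter pair; any record set spanning
#' both conditions is accepted (e.g. pooled across the grid for power
#' checks).
#'
#' @param records rows of [phylum_freq_records()] (usually one filter
#'   pair).
#' @return list with `model` (selected fit), `selected_terms`, `aic_trace`,
#'   and `estimates` (`data.frame` of per-phylum, per-condition fitted
#'   rates).
#' @export
fit_phylum_poisson <- function(records) {
  stopifnot(all(c("phylum", "condition", "n_fb") %in% names(records)))
  tot <- tapply(records$n_fb, records$phylum, sum)
  drop_ph <- names(tot)[tot == 0L]
  records <- records[!(records$phylum %in% drop_ph), , drop = FALSE]
  if (sum(records$n_fb) == 0L) stop("all fb counts are zero")
  if (length(unique(records$phylum)) < 2L) stop("need >= 2 phyla")
  if (length(unique(records$condition)) < 2L) {
    stop("both conditions are required to contrast snow cover")
  }
  records$phylum <- factor(records$phylum)
  records$condition <- factor(records$condition, levels = CONDITIONS)
  start <- glm(n_fb ~ phylum + condition, family = poisson(),
               data = records)
  sel <- stepwise_aic(start, lower = ~1, upper = ~ phylum * condition)
  grid <- expand.grid(phylum = levels(records$phylum),
                      condition = factor(CONDITIONS, levels = CONDITIONS))
  grid$rate <- predict(sel, newdata = grid, type = "response")
  list(model = sel,
       selected_terms = attr(terms(sel), "term.labels"),
       aic_trace = sel$anova,
       estimates = grid)
}

#' Condition rate ratio for one phylum from a Poisson fit
#'
#' Wald estimate and confidence interval for the snow-covered / snow-free
#' rate ratio of a given phylum, from the (possibly interaction-containing)
#' selected model.
#'
#' @param fit a `glm` Poisson fit as returned in
#'   `fit_phylum_poisson()$model`.
#' @param phylum phylum level to contrast.
#' @param level confidence level.
#' @return named vector `estimate`, `lower`, `upper` (ratio scale).
#' @export
phylum_rate_ratio <- function(fit, phylum, level = 0.95) {
  nd <- data.frame(
    phylum = factor(c(phylum, phylum), levels = levels(fit$model$phylum)),
    condition = factor(c("snow_covered", "snow_free"), levels = CONDITIONS))
  X <- model.matrix(delete.response(terms(fit)), nd)
  d <- X[1L, ] - X[2L, ]
  est <- sum(d * coef(fit))
  se <- sqrt(drop(t(d) %*% vcov(fit) %*% d))
  z <- qnorm(1 - (1 - level) / 2)
  c(estimate = exp(est), lower = exp(est - z * se),
    upper = exp(est + z * se))
}
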