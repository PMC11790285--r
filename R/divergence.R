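#' Empirical Pearson-like scaled Bregman divergence (PLsBD)
#'
#' Plug-in estimate of the Pearson-like scaled Bregman divergence of the
#' training density from the test density, measured relative to the mixture
#' \eqn{m_\alpha = \alpha p_{tr} + (1-\alpha) p_{te}}:
#' \deqn{\widehat{PL} = \frac{1}{2 n_{tr}} \sum_i \hat w(x^{tr}_i)
#'   - \frac{2-\alpha}{2(1-\alpha)} \frac{1}{n_{te}} \sum_j \hat w(x^{te}_j)
#'   + \frac{1}{2(1-\alpha)}.}
#' Both sample terms are averages of the estimated relative ratio
#' \eqn{\hat w_\alpha}; with \eqn{\hat w \equiv 1} (identical distributions)
#' the estimate is exactly zero. The mixture reference keeps the divergence
#' bounded for `alpha > 0`, which is the point of the construction.
#'
#' @param w_train Estimated ratio values at the training points.
#' @param w_test Estimated ratio values at the test points.
#' @param alpha Mixing weight in [0, 1); `alpha = 0` gives the empirical
#'   Pearson divergence \eqn{\frac{1}{2}\bar w_{tr} - \bar w_{te} +
#'   \frac{1}{2}}.
#' @return A single numeric divergence score (unnormalised).
#' @export
plsbd_score <- function(w_train, w_test, alpha) {
  alpha <- check_alpha(alpha)
  if (length(w_train) < 1L || length(w_test) < 1L) {
    abort_shape("`w_train` and `w_test` must be non-empty.")
  }
  m_tr <- mean(w_train)
  m_te <- mean(w_test)
  if (alpha == 0) {
    0.5 * m_tr - m_te + 0.5
  } else {
    # grouped so that m_tr = m_te = 1 yields exactly zero in floating point
    0.5 * m_tr - 0.5 * m_te + (1 - m_te) / (2 * (1 - alpha))
  }
}

#' Empirical alpha-relative Pearson divergence
#'
#' Plug-in estimate of the Pearson divergence between the training density
#' and the mixture \eqn{p_{te,\alpha}}, the score underlying RuLSIF:
#' \deqn{\widehat{PE}_\alpha = \frac{1}{2 n_{tr}} \sum_i \hat w(x^{tr}_i) -
#' \frac{1}{2}.} Only the training-sample average enters; the test sample
#' influences the score solely through the fitted ratio model.
#'
#' @param w_train Estimated ratio values at the training points.
#' @param alpha Mixing weight in [0, 1) (validated for interface consistency;
#'   it enters through the ratio model, not the formula).
#' @return A single numeric divergence score (unnormalised).
#' @export
alpha_pe_score <- function(w_train, alpha = 0) {
  alpha <- check_alpha(alpha)
  if (length(w_train) < 1L) abort_shape("`w_train` must be non-empty.")
  0.5 * mean(w_train) - 0.5
}

#' Score a train/test pair with a fitted ratio model
#'
#' Evaluates the fitted \eqn{\hat w} on the training points (and, for PLsBD,
#' the test points) and dispatches to the requested divergence. With
#' `divergence = "ALPHA_PE"`, `alpha = 0` and an L2-learned model this is the
#' uLSIF anomaly score.
#'
#' @param model A fitted [ratio_model()].
#' @param train,test The sample pair the model was fitted on.
#' @param divergence `"PLSBD"` or `"ALPHA_PE"`.
#' @param alpha Mixing weight; must equal `model$alpha`.
#' @return A single numeric divergence score.
#' @export
divergence_score <- function(model, train, test,
                             divergence = c("PLSBD", "ALPHA_PE"),
                             alpha = model$alpha) {
  divergence <- match.arg(divergence)
  alpha <- check_alpha(alpha)
  if (!isTRUE(all.equal(alpha, model$alpha))) {
    abort_inconsistent(sprintf(
      "divergence alpha (%g) differs from the model's alpha (%g).",
      alpha, model$alpha))
  }
  w_train <- estimate_ratio(model, train)
  if (divergence == "PLSBD") {
    plsbd_score(w_train, estimate_ratio(model, test), alpha)
  } else {
    alpha_pe_score(w_train, alpha)
  }
}
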