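#' Conditional probability table for source reports
#'
#' The epistemic core of the persuasion model: the probability that a source
#' endorses the hypothesis ("the micro-targeting candidate is the right
#' choice") in each of the eight combinations of hypothesis state (true or
#' false), trustworthiness (trustworthy or not) and expertise (expert or
#' not). The default entries are empirically derived conditional parameters
#' elicited from US voters.
#'
#' @param h,not_h Numeric vectors of length four giving \eqn{p(rep \mid \cdot)}
#'   when the hypothesis is true (`h`) and false (`not_h`), in column order
#'   (T, E), (T, ¬E), (¬T, E), (¬T, ¬E).
#'
#' @return A tibble of class `credibility_table` with columns `hypothesis`
#'   (`"H"`/`"notH"`), `trust`, `expertise` (logicals) and `p_rep`.
#' @examples
#' credibility_table()
#' @export
credibility_table <- function(h = c(0.80, 0.58, 0.34, 0.18),
                              not_h = c(0.22, 0.42, 0.59, 0.71)) {
  if (length(h) != 4L || length(not_h) != 4L) {
    abort("`h` and `not_h` must each have four entries: (T,E), (T,¬E), (¬T,E), (¬T,¬E).")
  }
  check_prob(h, "h")
  check_prob(not_h, "not_h")
  out <- tibble(
    hypothesis = rep(c("H", "notH"), each = 4L),
    trust      = rep(c(TRUE, TRUE, FALSE, FALSE), 2L),
    expertise  = rep(c(TRUE, FALSE, TRUE, FALSE), 2L),
    p_rep      = c(h, not_h)
  )
  class(out) <- c("credibility_table", class(out))
  out
}

# rows of the table as two 4-vectors in (T,E),(T,notE),(notT,E),(notT,notE) order
table_rows <- function(table) {
  if (!inherits(table, "credibility_table")) {
    abort("`table` must be created with `credibility_table()`.")
  }
  ord <- order(table$hypothesis, !table$trust, !table$expertise)
  tb <- table[ord, ]
  list(
    h     = tb$p_rep[tb$hypothesis == "H"],
    not_h = tb$p_rep[tb$hypothesis == "notH"]
  )
}

#' Marginal report likelihoods for a perceived source
#'
#' Integrates a voter's graded perception of a source's trustworthiness
#' \eqn{P(T)} and expertise \eqn{P(E)} over the conditional report table to
#' obtain the two likelihoods that drive Bayesian belief revision:
#' \eqn{p(rep \mid h)} and \eqn{p(rep \mid \neg h)}. Trust and expertise are
#' treated as independent, so each table entry is weighted by the product of
#' the corresponding state probabilities:
#' \deqn{p(rep \mid h) = \sum_{t \in \{T,\neg T\}} \sum_{e \in \{E,\neg E\}}
#'   p(rep \mid h, t, e)\, w(t)\, w(e)}
#' with \eqn{w(T) = P(T)}, \eqn{w(\neg T) = 1 - P(T)} and likewise for
#' expertise.
#'
#' @param trust,expertise Numeric vectors of subjective probabilities in
#'   \[0, 1\]; recycled to a common length.
#' @param table A [credibility_table()].
#'
#' @return A tibble with columns `p_rep_given_h` and `p_rep_given_not_h`.
#' @examples
#' marginal_likelihoods(trust = 0.6, expertise = 0.6)
#' @export
marginal_likelihoods <- function(trust, expertise, table = credibility_table()) {
  check_prob(trust, "trust")
  check_prob(expertise, "expertise")
  rows <- table_rows(table)
  te <- trust * expertise
  tn <- trust * (1 - expertise)
  ne <- (1 - trust) * expertise
  nn <- (1 - trust) * (1 - expertise)
  tibble(
    p_rep_given_h     = te * rows$h[1] + tn * rows$h[2] + ne * rows$h[3] + nn * rows$h[4],
    p_rep_given_not_h = te * rows$not_h[1] + tn * rows$not_h[2] + ne * rows$not_h[3] + nn * rows$not_h[4]
  )
}

#' Posterior belief after a persuasive message
#'
#' Bayesian belief revision given testimony from a source of perceived
#' credibility. For an endorsement,
#' \deqn{p(h \mid rep) = \frac{p(h)\,p(rep \mid h)}
#'   {p(h)\,p(rep \mid h) + p(\neg h)\,p(rep \mid \neg h)}.}
#' For an opposing message the source asserts the negated report, so each
#' likelihood \eqn{\ell} is replaced by \eqn{1 - \ell}. When both weighted
#' terms of the denominator vanish (possible only with degenerate
#' likelihoods) the prior is returned unchanged, with a warning.
#'
#' An endorsement raises belief exactly when
#' \eqn{p(rep \mid h) > p(rep \mid \neg h)}; when the inequality is reversed
#' the endorsement lowers belief — the backfire effect of a low-credibility
#' source.
#'
#' @param prior Numeric vector of prior beliefs in \[0, 1\].
#' @param p_rep_given_h,p_rep_given_not_h Report likelihoods, e.g. from
#'   [marginal_likelihoods()]; recycled against `prior`.
#' @param message `"endorse"` or `"oppose"`.
#'
#' @return Numeric vector of posterior beliefs in \[0, 1\].
#' @examples
#' lik <- marginal_likelihoods(trust = 1, expertise = 1)
#' posterior_belief(0.5, lik$p_rep_given_h, lik$p_rep_given_not_h, "endorse")
#' @export
posterior_belief <- function(prior, p_rep_given_h, p_rep_given_not_h,
                             message = c("endorse", "oppose")) {
  message <- match.arg(message)
  check_prob(prior, "prior")
  check_prob(p_rep_given_h, "p_rep_given_h")
  check_prob(p_rep_given_not_h, "p_rep_given_not_h")
  if (message == "oppose") {
    p_rep_given_h <- 1 - p_rep_given_h
    p_rep_given_not_h <- 1 - p_rep_given_not_h
  }
  num <- prior * p_rep_given_h
  den <- num + (1 - prior) * p_rep_given_not_h
  out <- num / den
  bad <- den == 0
  if (any(bad)) {
    warn("Zero denominator in belief update; returning the prior unchanged.")
    out[bad] <- rep_len(prior, length(out))[bad]
  }
  out
}

#' Credibility score of a perceived source
#'
#' The signalling score a micro-targeting campaign screens voters on: the
#' arithmetic mean of the voter's perceived trustworthiness and expertise of
#' the candidate.
#'
#' @inheritParams marginal_likelihoods
#' @return Numeric vector `(trust + expertise) / 2`.
#' @examples
#' credibility_score(0.4, 0.8)
#' @export
credibility_score <- function(trust, expertise) {
  check_prob(trust, "trust")
  check_prob(expertise, "expertise")
  (trust + expertise) / 2
}
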