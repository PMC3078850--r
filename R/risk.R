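#' Risk-model configuration
#'
#' Bundles the genetic and treatment parameters of the generative risk model:
#'
#' * `q` — population frequency of risk-allele carriers (default 0.59, the
#'   carrier frequency used throughout the reference experiments);
#' * `RR` — carrier risk ratio: carriers' event probability is `RR` times the
#'   baseline in the absence of treatment (1.50 and 1.25 are the canonical
#'   values);
#' * `s` — fraction of the whole population using statins, assigned at
#'   random independently of genotype, age and sex;
#' * `e` — fraction of the carrier *excess* risk eliminated by statin use
#'   (`e = 1`: treated carriers have exactly baseline risk; statins never
#'   change noncarrier risk in this model).
#'
#' @param q carrier frequency, in (0, 1).
#' @param RR carrier risk ratio, > 0.
#' @param s statin-use fraction, in \[0, 1\].
#' @param e fraction of carrier excess risk eliminated by statin, in \[0, 1\].
#' @return a `risk_config` list.
#' @examples
#' risk_config(RR = 1.25, s = 0.4)
#' @export
risk_config <- function(q = 0.59, RR = 1.5, s = 0, e = 1) {
  if (!(is.numeric(q) && length(q) == 1 && q > 0 && q < 1)) {
    stop("q must be strictly inside (0, 1)", call. = FALSE)
  }
  if (!(is.numeric(RR) && length(RR) == 1 && RR > 0)) {
    stop("RR must be a single positive number", call. = FALSE)
  }
  if (!(is.numeric(s) && length(s) == 1 && s >= 0 && s <= 1)) {
    stop("s must be in [0, 1]", call. = FALSE)
  }
  if (!(is.numeric(e) && length(e) == 1 && e >= 0 && e <= 1)) {
    stop("e must be in [0, 1]", call. = FALSE)
  }
  structure(list(q = q, RR = RR, s = s, e = e), class = "risk_config")
}

#' Assign carrier status at random
#'
#' Independent Bernoulli(`q`) carrier indicators; genotype is independent of
#' age, sex and treatment by construction. Uses the current RNG stream.
#'
#' @param n number of individuals.
#' @param q carrier frequency, strictly inside (0, 1).
#' @return integer 0/1 vector of length `n`.
#' @export
assign_genotype <- function(n, q = 0.59) {
  if (!(q > 0 && q < 1)) {
    stop("q must be strictly inside (0, 1)", call. = FALSE)
  }
  as.integer(runif(n) < q)
}

#' Assign statin use at random
#'
#' Independent Bernoulli(`s`) treatment indicators, independent of genotype,
#' age and sex. `s = 0` returns all zeros without consuming random numbers'
#' worth of variation in expectation (a draw is still made per individual so
#' downstream streams are unaffected by the value of `s`).
#'
#' @param n number of individuals.
#' @param s statin-use fraction in \[0, 1\].
#' @return integer 0/1 vector of length `n`.
#' @export
assign_statin <- function(n, s = 0) {
  if (!(s >= 0 && s <= 1)) {
    stop("s must be in [0, 1]", call. = FALSE)
  }
  as.integer(runif(n) < s)
}

#' Per-individual event probability
#'
#' The generative risk of an individual is the baseline cumulative incidence
#' for their age and sex multiplied by a genotype/treatment factor:
#' `m = 1` for noncarriers (statin or not), and
#' `m = 1 + (RR - 1) * (1 - e * statin)` for carriers, so an untreated
#' carrier has `RR` times baseline risk and a treated carrier retains the
#' fraction `1 - e` of the excess. Results are clipped to `[0, 1 - 1e-12]`;
#' the number of clipped values is recorded in the `"clipped"` attribute
#' (with a sanely calibrated surface it is always 0).
#'
#' @param age integer ages (vector).
#' @param sex `"F"`/`"M"` (vector).
#' @param carrier 0/1 carrier indicators.
#' @param statin 0/1 statin indicators.
#' @param incidence an `incidence_table`.
#' @param cfg a `risk_config` (or any list with `RR`, `e`).
#' @return numeric event probabilities with attribute `clipped`.
#' @examples
#' inc <- load_incidence()
#' individual_risk(65, "M", carrier = 1, statin = 0, inc, risk_config())
#' @export
individual_risk <- function(age, sex, carrier, statin, incidence, cfg) {
  lut <- incidence_lookup(incidence)
  min_age <- attr(lut, "min_age")
  max_age <- attr(lut, "max_age")
  if (any(age < min_age | age > max_age)) {
    bad <- which(age < min_age | age > max_age)[1]
    stop("age ", age[bad], " outside the incidence table range [",
         min_age, ", ", max_age, "]", call. = FALSE)
  }
  p0 <- lut[cbind(age - min_age + 1L, ifelse(sex == "M", 2L, 1L))]
  mult <- 1 + (cfg$RR - 1) * carrier * (1 - cfg$e * statin)
  p <- p0 * mult
  clipped <- sum(p > 1 - 1e-12 | p < 0)
  p <- pmin(pmax(p, 0), 1 - 1e-12)
  attr(p, "clipped") <- clipped
  p
}
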