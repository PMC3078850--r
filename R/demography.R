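#' Load and validate a banded age-by-sex population distribution
#'
#' A demography table gives the fraction of the simulated source population in
#' each half-open age band `[age_lo, age_hi)` by sex. It is the sampling frame
#' for cohort synthesis: individuals are drawn by multinomial band/sex
#' selection and then given a uniform integer age within the band.
#'
#' `source` is either the name of a packaged fixture or a path to a CSV with
#' columns `age_lo, age_hi, sex, proportion` (`sex` coded `F`/`M`, header
#' required). The packaged `"canada2006"` fixture is an approximation of the
#' 2006 Canadian census age/sex structure for ages 40-89 in 5-year bands,
#' committed as a synthetic, replaceable data file: simulated selection bias is
#' insensitive to moderate changes in the population pyramid, so an
#' approximation is adequate, but the values should not be treated as census
#' data.
#'
#' Proportions must be non-negative and sum to 1; a deviation of at most
#' `1e-6` is repaired by a single renormalization pass, anything larger is an
#' error. Bands must not overlap within a sex and both sexes must be present.
#'
#' @param source `"canada2006"` or a CSV file path.
#' @return a `demography_table`: a data.frame with columns
#'   `age_lo, age_hi, sex, proportion`.
#' @seealso [sample_population()]
#' @examples
#' demog <- load_demography("canada2006")
#' sum(demog$proportion)
#' @export
load_demography <- function(source = "canada2006") {
  path <- if (identical(source, "canada2006")) {
    system.file("extdata", "canada2006_synthetic.csv", package = "survbiasim",
                mustWork = TRUE)
  } else {
    source
  }
  if (!file.exists(path)) {
    stop("demography source not found: ", source, call. = FALSE)
  }
  tab <- read.csv(path, stringsAsFactors = FALSE)
  # a column of bare "F" parses as logical; restore the character coding
  if (is.logical(tab$sex)) tab$sex <- ifelse(tab$sex, "T", "F")
  required <- c("age_lo", "age_hi", "sex", "proportion")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("demography file is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tab <- tab[required]
  tab$sex <- toupper(as.character(tab$sex))
  validate_demography(tab)
}

validate_demography <- function(tab) {
  if (!all(tab$sex %in% c("F", "M"))) {
    bad <- which(!tab$sex %in% c("F", "M"))[1]
    stop("demography row ", bad, ": sex must be 'F' or 'M', got '",
         tab$sex[bad], "'", call. = FALSE)
  }
  if (!all(c("F", "M") %in% tab$sex)) {
    stop("demography table must contain both sexes", call. = FALSE)
  }
  if (any(tab$age_hi <= tab$age_lo)) {
    bad <- which(tab$age_hi <= tab$age_lo)[1]
    stop("demography row ", bad, ": empty age band [", tab$age_lo[bad], ",",
         tab$age_hi[bad], ")", call. = FALSE)
  }
  if (any(tab$proportion < 0)) {
    bad <- which(tab$proportion < 0)[1]
    stop("demography row ", bad, ": negative proportion ",
         tab$proportion[bad], call. = FALSE)
  }
  # non-overlap within each sex (bands are half-open)
  for (sx in c("F", "M")) {
    rows <- which(tab$sex == sx)
    o <- rows[order(tab$age_lo[rows])]
    if (length(o) > 1) {
      overlap <- which(tab$age_lo[o][-1] < tab$age_hi[o][-length(o)])
      if (length(overlap)) {
        stop("demography row ", o[overlap[1] + 1], ": age band overlaps the ",
             "preceding band for sex ", sx, call. = FALSE)
      }
    }
  }
  s <- sum(tab$proportion)
  if (abs(s - 1) > 1e-6) {
    stop("demography proportions sum to ", format(s, digits = 10),
         "; must equal 1 within 1e-6", call. = FALSE)
  }
  if (abs(s - 1) > 1e-9) {
    tab$proportion <- tab$proportion / s
  }
  structure(tab, class = c("demography_table", "data.frame"))
}

#' Sample ages and sexes for a simulated cohort
#'
#' Draws `n` individuals from a demography table: band-by-sex cells are
#' selected multinomially with the table's proportions, then an integer age is
#' drawn uniformly within the selected half-open band. Uses the current R
#' random stream; call [set.seed()] (or rely on the [stage_seed()] ladder via
#' [simulate_cohort()]) for reproducibility.
#'
#' @param demog a `demography_table` from [load_demography()].
#' @param n number of individuals (>= 1).
#' @return a data.frame with integer `age` and character `sex` (`"F"`/`"M"`),
#'   one row per individual.
#' @examples
#' demog <- load_demography("canada2006")
#' set.seed(1)
#' head(sample_population(demog, 5))
#' @export
sample_population <- function(demog, n) {
  stopifnot(inherits(demog, "demography_table"))
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    stop("n must be a single count >= 1", call. = FALSE)
  }
  n <- as.integer(n)
  cell <- sample.int(nrow(demog), n, replace = TRUE, prob = demog$proportion)
  lo <- demog$age_lo[cell]
  width <- demog$age_hi[cell] - lo
  age <- as.integer(lo + floor(runif(n) * width))
  data.frame(age = age, sex = demog$sex[cell], stringsAsFactors = FALSE)
}

#' @export
print.demography_table <- function(x, ...) {
  cat("Demography table: ", nrow(x), " band-by-sex cells, ages [",
      min(x$age_lo), ",", max(x$age_hi), ")\n", sep = "")
  NextMethod()
}
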