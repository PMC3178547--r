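#' Expected SNP-array signals for an allelic state under stromal contamination
#'
#' The signal model treats an observed sample as a mixture of tumour cells
#' carrying `major + minor` copies of a locus and diploid, heterozygous
#' normal (stromal) cells at fraction `rho`.  With normalisation ploidy
#' `c_tilde` (the total copy number that maps to a normalised total ratio of
#' 1), the expectations are
#'
#' \deqn{c_{tot} = 2\rho + (1-\rho)(a+b), \quad
#'       c_{str} = \rho + (1-\rho)a,}
#' \deqn{t = c_{tot} / (2\rho + (1-\rho)\tilde c), \quad
#'       f = c_{str} / c_{tot}}
#'
#' where `t` is the normalised total ratio and `f` the mirrored (strongest)
#' allele fraction at germline-heterozygous markers.  `f` is defined as 1
#' when the total mixed copy number is 0.
#'
#' All arguments are vectorised over `major`/`minor`.
#'
#' @param major,minor integer allele copy numbers, `major >= minor >= 0`.
#' @param rho stromal contamination fraction in `[0, 1)`.
#' @param c_tilde normalisation ploidy (> 0).
#' @return data.frame with columns `t` and `mirrored`.
#' @export
#' @examples
#' expected_signals(2, 0, rho = 0.3, c_tilde = 2)   # t = 1, mirrored = 0.85
expected_signals <- function(major, minor, rho, c_tilde) {
  stopifnot(rho >= 0, rho < 1, c_tilde > 0)
  if (any(minor > major)) stop("'major' must be >= 'minor'")
  if (any(minor < 0)) stop("copy numbers must be non-negative")
  c_tot <- 2 * rho + (1 - rho) * (major + minor)
  c_str <- rho + (1 - rho) * major
  c_norm <- 2 * rho + (1 - rho) * c_tilde
  mirrored <- ifelse(c_tot > 0, c_str / c_tot, 1)
  data.frame(t = c_tot / c_norm, mirrored = mirrored)
}

# All candidate allelic states (a, b) with b <= a <= max_copies, ordered so
# that which.min() resolves ties toward smaller total, then larger minor.
enumerate_states <- function(max_copies = 12L) {
  g <- expand.grid(minor = 0:max_copies, major = 0:max_copies)
  g <- g[g$minor <= g$major, c("major", "minor")]
  g$total <- g$major + g$minor
  g <- g[order(g$total, -g$minor), ]
  rownames(g) <- NULL
  g
}

balanced_state <- function(total) {
  data.frame(major = ceiling(total / 2), minor = floor(total / 2))
}

# Expected value of the observed mirrored fraction max(X, 1-X) when the
# underlying fraction is f and markers carry Gaussian noise of SD sigma.
# Near f = 0.5 folding inflates the mean (to 0.5 + sigma*sqrt(2/pi) at
# exactly 0.5); ignoring this biases the state fit toward spuriously
# imbalanced states.  sigma = 0 returns f unchanged.
mirrored_expectation <- function(f, sigma) {
  if (length(sigma) != 1 || sigma <= 0) return(f)
  z <- (0.5 - f) / sigma
  f + (1 - 2 * f) * stats::pnorm(z) + 2 * sigma * stats::dnorm(z)
}
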