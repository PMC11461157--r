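#' Life table of annual non-CRC death probabilities
#'
#' A life table is a data frame with integer column `age` (contiguous) and
#' column `q`, the annual probability of death from causes other than
#' colorectal cancer. The final row must have `q = 1` so every simulated
#' person dies by the closing age.
#'
#' @param age integer vector of contiguous ages.
#' @param q numeric vector of annual death probabilities in `[0, 1]`;
#'   the last element must be 1.
#' @return a `data.frame` of class `crc_life_table`.
#' @examples
#' lt <- life_table(45:100, c(rep(0.01, 55), 1))
#' life_expectancy(lt)
#' @export
life_table <- function(age, q) {
  age <- as.integer(age)
  q <- as.numeric(q)
  if (length(age) != length(q) || length(age) < 2L)
    stop("life_table: 'age' and 'q' must have equal length >= 2")
  if (any(diff(age) != 1L))
    stop("life_table: ages must be contiguous integer years")
  if (any(q < 0 | q > 1) || any(!is.finite(q)))
    stop("life_table: 'q' must lie in [0, 1]")
  if (q[length(q)] != 1)
    stop("life_table: final age must have q = 1")
  out <- data.frame(age = age, q = q)
  class(out) <- c("crc_life_table", "data.frame")
  out
}

#' Read a life table from CSV
#'
#' Expects a header `age,q` with one row per integer age.
#'
#' @param path path to a CSV file.
#' @return a `crc_life_table`.
#' @export
read_life_table <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("age", "q") %in% names(df)))
    stop("life-table CSV must have columns 'age' and 'q'")
  life_table(df$age, df$q)
}

#' Default Gompertz-Makeham other-cause mortality table
#'
#' Renders the Gompertz-Makeham hazard `mu(a) = A + B * exp(theta * a)` to an
#' annual life table on `[from, to]` with `q(to) = 1`. The default constants
#' are chosen so that remaining life expectancy at age 45 is about 37 years,
#' in line with a modern US average-risk cohort, without requiring any
#' external data file. Override with [read_life_table()] for a cohort table.
#'
#' @param A Makeham (age-independent) hazard component.
#' @param B,theta Gompertz senescence parameters.
#' @param from,to first and closing integer age of the table.
#' @return a `crc_life_table`.
#' @export
gompertz_makeham_life_table <- function(A = 8e-4, B = 2.75e-5, theta = 0.092,
                                        from = 45L, to = 100L) {
  stopifnot(A >= 0, B >= 0, theta > 0, to > from)
  age <- seq.int(from, to)
  # integrated hazard over [a, a+1]
  cumhaz <- A + (B / theta) * exp(theta * age) * (exp(theta) - 1)
  q <- 1 - exp(-cumhaz)
  q[length(q)] <- 1
  life_table(age, q)
}

#' Remaining life expectancy implied by a life table
#'
#' Deterministic expectation of the death age for a person alive at the first
#' table age, assuming deaths occur uniformly within the year (the same
#' convention the simulator uses when drawing continuous death ages).
#'
#' @param lt a `crc_life_table`.
#' @return expected remaining years of life at the first table age.
#' @export
life_expectancy <- function(lt) {
  p_die <- death_year_pmf(lt)
  sum(p_die * (lt$age + 0.5)) - lt$age[1L]
}

# probability of dying within each table year, conditional on being alive at
# the first table age
death_year_pmf <- function(lt) {
  surv <- cumprod(1 - lt$q)
  p <- c(lt$q[1L], diff(-surv) * 0 + utils::head(surv, -1L) * lt$q[-1L])
  p
}

# Draw continuous death ages by inverse CDF: one uniform per person selects
# the death year and, through its residual mass, the position within the year.
sample_death_age <- function(lt, u) {
  p <- death_year_pmf(lt)
  cdf <- cumsum(p)
  cdf[length(cdf)] <- 1
  idx <- findInterval(u, cdf) + 1L
  idx[idx > length(p)] <- length(p)
  lower <- c(0, cdf)[idx]
  frac <- (u - lower) / p[idx]
  frac[!is.finite(frac)] <- 0.5
  lt$age[idx] + pmin(pmax(frac, 0), 1)
}
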