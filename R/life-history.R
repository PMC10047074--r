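#' Read a life-history table
#'
#' CSV with columns `id`, `birth_year`, `dellbridge` (0/1 birth-colony
#' indicator), `pup_ages` (semicolon-separated maternal ages at pupping)
#' and `last_observed_age`.
#'
#' @param path CSV path.
#' @param horizon observation horizon in years (study default 19).
#' @return data.frame with a parsed `pup_ages` list-column.
#' @export
readLifeHistories <- function(path, horizon = 19) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "birth_year", "dellbridge", "pup_ages",
            "last_observed_age")
  if (!all(need %in% names(df)))
    stop("life-history file must contain: ", paste(need, collapse = ", "))
  df$pup_ages <- lapply(strsplit(as.character(df$pup_ages), ";"),
                        function(x) sort(as.integer(x)))
  df$horizon <- horizon
  .validateLifeHistories(df)
  df
}

.validateLifeHistories <- function(df) {
  for (i in seq_len(nrow(df))) {
    ages <- df$pup_ages[[i]]
    if (!length(ages))
      stop("individual '", df$id[i], "' has no pups; only reproductive ",
           "females enter the analysis")
    if (any(ages < 4) || any(ages > df$horizon[i]))
      stop("individual '", df$id[i], "': pup age outside [4, horizon]")
    if (df$last_observed_age[i] < max(ages))
      stop("individual '", df$id[i],
           "': last observed age precedes a pupping age")
  }
  invisible(df)
}

#' Derive the four fitness responses from life histories
#'
#' Builds the per-individual responses of the four fitness models:
#' the Leslie-matrix instantaneous growth rate `r_i`, the death age
#' (censored at the horizon), the age at first reproduction, and the
#' successive pupping intervals with a first-interval flag.
#'
#' @param lifeHistories data.frame as returned by [readLifeHistories()] (or
#'   built in code with a `pup_ages` list-column).
#' @return list of data.frames: `ri` (id, ri, censored_at_max, col, year),
#'   `death` (id, age, censored, col, year), `afr` (id, afr, col, year) and
#'   `wait` (id, wait, first, col, year).
#' @export
deriveResponses <- function(lifeHistories) {
  df <- .validateLifeHistories(lifeHistories)
  n <- nrow(df)
  horizon <- df$horizon[1]
  upper <- maxGrowthRateBound(horizon, 4)
  riL <- deathL <- afrL <- list()
  waitL <- list()
  for (i in seq_len(n)) {
    ages <- df$pup_ages[[i]]
    id <- df$id[i]; col <- df$dellbridge[i]; yr <- df$birth_year[i]
    ri <- individualGrowthRate(ages, horizon)
    riL[[i]] <- data.frame(id = id, ri = ri,
                           censored_at_max = (abs(ri - upper) < 1e-9),
                           col = col, year = yr)
    cens <- df$last_observed_age[i] >= horizon
    deathL[[i]] <- data.frame(
      id = id, age = if (cens) horizon else df$last_observed_age[i],
      censored = cens, col = col, year = yr)
    afrL[[i]] <- data.frame(id = id, afr = min(ages), col = col, year = yr)
    if (length(ages) > 1) {
      w <- diff(ages)
      waitL[[length(waitL) + 1]] <- data.frame(
        id = id, wait = w,
        first = as.integer(seq_along(w) == 1), col = col, year = yr)
    }
  }
  list(ri = do.call(rbind, riL), death = do.call(rbind, deathL),
       afr = do.call(rbind, afrL),
       wait = if (length(waitL)) do.call(rbind, waitL) else
         data.frame(id = character(), wait = integer(), first = integer(),
                    col = numeric(), year = integer()))
}

#' Individual Leslie matrix for a pupping schedule
#'
#' Age-classified projection matrix with unit survival on the sub-diagonal
#' and fecundity one at class `a - 1` for a pup at maternal age `a`, so the
#' characteristic equation is `sum(lambda^-(a-1)) = 1` over the pup ages.
#' Under this convention a single pup gives dominant eigenvalue exactly 1
#' (growth rate zero) and the maximal 19-year schedule gives the censoring
#' bound used by the fitness model.
#'
#' @param pupAges integer maternal ages at pupping (each >= 2).
#' @param horizon observation horizon; pup ages must not exceed it.
#' @return square non-negative matrix.
#' @export
leslieMatrix <- function(pupAges, horizon = 19) {
  pupAges <- sort(unique(as.integer(pupAges)))
  if (!length(pupAges)) stop("pupAges must be non-empty")
  if (any(pupAges < 2) || any(pupAges > horizon))
    stop("pup ages must lie in [2, horizon]")
  m <- max(pupAges) - 1L
  M <- matrix(0, m, m)
  M[1, pupAges - 1L] <- 1
  if (m > 1) M[cbind(2:m, 1:(m - 1))] <- 1
  M
}

# unique positive root of sum(lambda^-(a-1)) = 1; the function is strictly
# decreasing on (0, Inf) so bisection via uniroot is safe
.dominantLambda <- function(pupAges) {
  pupAges <- sort(unique(as.integer(pupAges)))
  if (length(pupAges) == 1) return(1)
  g <- function(lam) sum(lam^(-(pupAges - 1))) - 1
  uniroot(g, lower = 1, upper = length(pupAges) + 1, tol = 1e-14)$root
}

#' Individual-based instantaneous growth rate
#'
#' Natural log of the dominant eigenvalue of [leslieMatrix()]; zero for a
#' single pup, and bounded above by [maxGrowthRateBound()] for schedules
#' within the horizon.
#'
#' @inheritParams leslieMatrix
#' @return non-negative growth rate.
#' @export
individualGrowthRate <- function(pupAges, horizon = 19) {
  leslieMatrix(pupAges, horizon)  # validates
  log(.dominantLambda(pupAges))
}

#' Maximum observable growth rate for a horizon
#'
#' Growth rate of the schedule producing one pup every year from the
#' minimum age at first reproduction through the horizon; for the study
#' design (horizon 19, maturity at 4) this is the censoring bound of the
#' lifetime-reproductive-success model.
#'
#' @param horizon observation horizon.
#' @param minAfr minimum age at first reproduction (population minimum 4).
#' @return maximal growth rate.
#' @export
maxGrowthRateBound <- function(horizon = 19, minAfr = 4) {
  stopifnot(minAfr <= horizon)
  individualGrowthRate(seq(minAfr, horizon), horizon)
}
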