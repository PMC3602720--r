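# Longitudinal panel records: validation, pattern classification, I/O.
#
# The panel dialect is one row per observation: columns id, age, state
# (1 = healthy, 2 = history of illness, 3 = death), death (0/1 exact-death
# indicator, 1 only on a terminal state-3 row), then any baseline covariate
# columns. An individual right censored alive is censored at the age of the
# last row (no separate censoring row is required; a final row with
# death = 0 and the last observed living state marks the censoring age when
# the vital-status follow-up extends past the last interview).

#' Assemble an analysable panel from a long-format data frame
#'
#' Validates one-row-per-observation longitudinal data and derives, per
#' individual, the anchors used by the likelihood: the baseline age `A_b`,
#' the last age observed healthy `A_1N`, the first age observed ill `A_20`,
#' the end of follow-up `A_N`, and the observation pattern A-F.
#'
#' Patterns: A/B = healthy at baseline, illness observed during follow-up,
#' then death (A) or right censoring (B); C/D = healthy at every
#' observation, then death (C) or censoring (D); E/F = already ill at
#' baseline (left-censored onset), then death (E) or censoring (F).
#'
#' @param df A data frame with columns `id`, `age`, `state`, `death` and
#'   optionally covariate columns.
#' @param covariates Character vector of covariate column names to carry
#'   (baseline values are used).
#' @return An object of class `smid_panel`: a list of per-individual
#'   records plus attributes.
#' @export
smid_panel <- function(df, covariates = character(0)) {
  need <- c("id", "age", "state")
  if (!all(need %in% names(df))) stop("panel needs columns id, age, state")
  if (is.null(df$death)) df$death <- as.integer(df$state == 3)
  miss <- setdiff(covariates, names(df))
  if (length(miss)) stop("missing covariate columns: ", paste(miss, collapse = ", "))
  recs <- lapply(split(df, df$id, drop = TRUE), make_record, covariates = covariates)
  bad <- vapply(recs, function(r) !is.null(r$error), logical(1))
  if (any(bad)) {
    msgs <- vapply(recs[bad], function(r) paste0("id ", r$id, ": ", r$error), "")
    stop("invalid records:\n  ", paste(msgs, collapse = "\n  "))
  }
  structure(recs, class = "smid_panel", covariates = covariates)
}

make_record <- function(d, covariates) {
  d <- d[order(d$age), , drop = FALSE]
  id <- d$id[1L]
  fail <- function(msg) list(id = id, error = msg)
  if (any(diff(d$age) <= 0)) return(fail("ages not strictly increasing"))
  st <- as.integer(d$state)
  if (!all(st %in% 1:3)) return(fail("states must be 1, 2 or 3"))
  if (any(diff(st) < 0)) return(fail("recovery transition (state decreases)"))
  if (st[1L] == 3L) return(fail("baseline state is death"))
  if (sum(st == 3L) > 1L) return(fail("more than one death row"))
  dead <- any(st == 3L) || any(d$death == 1)
  if (any(st == 3L) && which(st == 3L) != length(st))
    return(fail("death row is not terminal"))
  Ab <- d$age[1L]
  AN <- d$age[length(st)]
  visits <- d[st != 3L, , drop = FALSE]
  A1N <- if (any(visits$state == 1)) max(visits$age[visits$state == 1]) else NA_real_
  A20 <- if (any(visits$state == 2)) min(visits$age[visits$state == 2]) else NA_real_
  x <- if (length(covariates)) unlist(d[1L, covariates, drop = TRUE]) else numeric(0)
  rec <- list(id = id, Ab = Ab, AN = AN, dead = dead,
              visit_age = visits$age, visit_state = as.integer(visits$state),
              A1N = A1N, A20 = A20, x = as.numeric(x))
  rec$pattern <- classify_pattern(rec)
  rec
}

#' Classify an individual's observation pattern
#'
#' @param record A single record as produced inside [smid_panel] (a list
#'   with elements `visit_state`, `dead`, `A1N`, `A20`).
#' @return One of `"A"`, `"B"`, `"C"`, `"D"`, `"E"`, `"F"`.
#' @export
classify_pattern <- function(record) {
  base_ill <- record$visit_state[1L] == 2L
  seen_ill <- !is.na(record$A20)
  if (base_ill) {
    if (record$dead) "E" else "F"
  } else if (seen_ill) {
    if (record$dead) "A" else "B"
  } else {
    if (record$dead) "C" else "D"
  }
}

patterns_of <- function(panel) vapply(panel, `[[`, "", "pattern")

#' @export
print.smid_panel <- function(x, ...) {
  pat <- table(factor(patterns_of(x), levels = LETTERS[1:6]))
  cat("Longitudinal illness-death panel:", length(x), "individuals\n")
  cat("patterns:", paste(names(pat), pat, sep = "=", collapse = "  "), "\n")
  cv <- attr(x, "covariates")
  if (length(cv)) cat("covariates:", paste(cv, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.smid_panel <- function(x, ...) {
  cv <- attr(x, "covariates")
  do.call(rbind, lapply(unname(x), function(r) {
    n_v <- length(r$visit_age)
    ages <- r$visit_age
    states <- r$visit_state
    death <- rep(0L, n_v)
    if (r$dead) {
      ages <- c(ages, r$AN)
      states <- c(states, 3L)
      death <- c(death, 1L)
    } else if (r$AN > ages[n_v] + 1e-12) {
      ages <- c(ages, r$AN)
      states <- c(states, states[n_v])
      death <- c(death, 0L)
    }
    out <- data.frame(id = r$id, age = ages, state = states, death = death)
    if (length(cv))
      out[cv] <- as.data.frame(matrix(rep(r$x, each = nrow(out)), nrow = nrow(out)))
    out
  }))
}

#' Read a longitudinal panel from a delimited text file
#'
#' @param path CSV file with header `id, age, state, death` plus optional
#'   covariate columns.
#' @param covariates Covariate column names to use.
#' @return A [smid_panel].
#' @export
read_panel <- function(path, covariates = character(0)) {
  df <- utils::read.csv(path, comment.char = "#")
  smid_panel(df, covariates = covariates)
}

#' Write a panel (or panel data frame) to CSV
#'
#' @param panel A [smid_panel] or a data frame in the panel dialect.
#' @param path Output file path.
#' @export
write_panel <- function(panel, path) {
  df <- if (is.data.frame(panel)) panel else as.data.frame(panel)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

subset_panel <- function(panel, keep) {
  structure(panel[keep], class = "smid_panel",
            covariates = attr(panel, "covariates"))
}
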