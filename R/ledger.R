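# Per-stage bookkeeping of the filtering funnel: every stage records how many
# records came in, how many were retained and a histogram of discard reasons.

#' Create an empty stage ledger
#'
#' @return object of class `stage_ledger`.
#' @export
stage_ledger <- function() {
  structure(list(stages = character(0), input = integer(0),
                 retained = integer(0), discarded = integer(0),
                 reasons = list()),
            class = "stage_ledger")
}

#' Append one stage to a ledger
#'
#' @param ledger a [stage_ledger()].
#' @param stage stage name.
#' @param input number of records entering the stage.
#' @param retained number retained.
#' @param reasons named integer vector (discard-reason histogram); must sum to
#'   `input - retained`.
#' @return the extended ledger.
#' @export
ledger_add <- function(ledger, stage, input, retained,
                       reasons = setNames(integer(0), character(0))) {
  stopifnot(inherits(ledger, "stage_ledger"))
  discarded <- input - retained
  if (length(reasons) == 0L && discarded > 0L)
    reasons <- setNames(as.integer(discarded), stage)
  ledger$stages <- c(ledger$stages, stage)
  ledger$input <- c(ledger$input, as.integer(input))
  ledger$retained <- c(ledger$retained, as.integer(retained))
  ledger$discarded <- c(ledger$discarded, as.integer(discarded))
  ledger$reasons <- c(ledger$reasons, list(reasons))
  ledger
}

#' @export
print.stage_ledger <- function(x, ...) {
  print(as.data.frame(x))
  invisible(x)
}

#' @export
as.data.frame.stage_ledger <- function(x, ...) {
  data.frame(stage = x$stages, input = x$input, retained = x$retained,
             discarded = x$discarded, stringsAsFactors = FALSE)
}

#' Validate a stage ledger
#'
#' Checks, at every stage, that `input = retained + discarded`, that counts
#' are non-negative, that the discard-reason histogram sums to the discarded
#' count, and that `retained(i) = input(i+1)` across consecutive stages.
#' Violations are returned as data, not raised as conditions.
#'
#' @param ledger a [stage_ledger()].
#' @return character vector of violation messages; empty when consistent.
#' @export
validate_ledger <- function(ledger) {
  stopifnot(inherits(ledger, "stage_ledger"))
  v <- character(0)
  n <- length(ledger$stages)
  for (i in seq_len(n)) {
    s <- ledger$stages[i]
    if (any(c(ledger$input[i], ledger$retained[i], ledger$discarded[i]) < 0L))
      v <- c(v, sprintf("stage %s: negative count", s))
    if (ledger$input[i] != ledger$retained[i] + ledger$discarded[i])
      v <- c(v, sprintf("stage %s: input %d != retained %d + discarded %d",
                        s, ledger$input[i], ledger$retained[i],
                        ledger$discarded[i]))
    hist_sum <- sum(ledger$reasons[[i]])
    if (ledger$discarded[i] > 0L && hist_sum != ledger$discarded[i])
      v <- c(v, sprintf("stage %s: reason histogram sums to %d, discarded %d",
                        s, hist_sum, ledger$discarded[i]))
    if (i < n && ledger$retained[i] != ledger$input[i + 1L])
      v <- c(v, sprintf("stage %s -> %s: retained %d != next input %d",
                        s, ledger$stages[i + 1L], ledger$retained[i],
                        ledger$input[i + 1L]))
  }
  v
}

# serializable form for the JSON run summary
ledger_to_list <- function(ledger) {
  lapply(seq_along(ledger$stages), function(i) list(
    stage = ledger$stages[i],
    input = ledger$input[i],
    retained = ledger$retained[i],
    discarded = ledger$discarded[i],
    reasons = as.list(ledger$reasons[[i]])
  ))
}

# tabulate a reason vector into a named integer histogram
reason_histogram <- function(reasons) {
  if (length(reasons) == 0L) return(setNames(integer(0), character(0)))
  tab <- table(reasons)
  setNames(as.integer(tab), names(tab))
}
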