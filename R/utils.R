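#' Build residue keys from chain, sequence number and insertion code
#'
#' @param chain chain identifiers.
#' @param resno integer author sequence numbers.
#' @param icode insertion codes (\code{""} or \code{NA} when absent).
#' @return character vector \code{"<chain>:<resno>[icode]"}.
#' @export
makeResidueKey <- function(chain, resno, icode = "") {
  icode <- ifelse(is.na(icode) | icode == " ", "", icode)
  paste0(chain, ":", resno, icode)
}

#' Default factor VIII domain map
#'
#' Maps legacy mature-protein positions to the canonical FVIII domain
#' architecture: A1 (1-336), a1 (337-372), A2 (373-710), a2 (711-740),
#' A3 (1649-2019, including the a3 acidic segment), C1 (2020-2172),
#' C2 (2173-2332). Positions in the B domain (741-1648) are unlabeled;
#' B-domain-deleted constructs such as the 2R7E structure do not contain
#' them.
#'
#' @param positions integer vector of legacy mature positions.
#' @return character vector of domain labels (\code{NA} where unlabeled).
#' @export
fviiiDomain <- function(positions) {
  stopifnot(is.numeric(positions))
  breaks <- c(1, 337, 373, 711, 741, 1649, 2020, 2173, 2333)
  labels <- c("A1", "a1", "A2", "a2", NA, "A3", "C1", "C2")
  idx <- findInterval(positions, breaks)
  out <- rep(NA_character_, length(positions))
  ok <- idx >= 1 & idx <= length(labels)
  out[ok] <- labels[idx[ok]]
  out
}

# internal: condition-based log messages, silenced via suppressMessages()
.logInfo <- function(...) message(sprintf(...))

# midpoint of a numeric range string "a to b"; NA when not a range
.parseRange <- function(x) {
  m <- regmatches(x, regexec("^\\s*(-?[0-9.]+)\\s+to\\s+(-?[0-9.]+)\\s*$", x))[[1]]
  if (length(m) == 3L) c(as.numeric(m[2]), as.numeric(m[3])) else NULL
}
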