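# Hemophilia A clinical mutation table sanitation and positional
# enrichment tests.
#
# The raw table emulates a curated hemophilia mutation database export:
# mutation type, variant effect, legacy mature-protein position, free-text
# FVIII:C activity strings (with ranges, bound markers and unicode spacing),
# optional duplicate assay columns, and reported severity.

.SEVERITY_BANDS <- c(severe_max = 1, moderate_max = 5, mild_max = 40)

# severity band of a numeric FVIII:C percent (standard hemophilia A bands:
# severe < 1, moderate 1-5, mild > 5-40, above 40 considered non-hemophilic)
.severityBand <- function(v) {
  ifelse(v < .SEVERITY_BANDS[["severe_max"]], "severe",
  ifelse(v <= .SEVERITY_BANDS[["moderate_max"]], "moderate",
  ifelse(v <= .SEVERITY_BANDS[["mild_max"]], "mild", "normal")))
}

# normalize whitespace (incl. non-breaking spaces) around an activity string
.normActivity <- function(x) {
  x <- gsub("\u00a0", " ", x)
  trimws(gsub("\\s+", " ", x))
}

# parse one activity string. Returns list(value=, rule=) where rule is NA
# for plain parses, the substitution rule applied, or one of the drop rules
# ("ambiguous_range", "non_numeric", "missing_activity") with value NA.
.parseActivity <- function(x) {
  x <- .normActivity(x)
  if (is.na(x) || x == "") return(list(value = NA_real_, rule = "missing_activity"))
  compact <- gsub(" ", "", x)
  bounds <- c("<1" = 0, ">5" = 5, "<10" = 10, "<11" = 11)
  if (compact %in% names(bounds)) {
    return(list(value = unname(bounds[compact]), rule = paste0("bound:", compact)))
  }
  rng <- .parseRange(x)
  if (!is.null(rng)) {
    if (.severityBand(rng[1]) != .severityBand(rng[2])) {
      return(list(value = NA_real_, rule = "ambiguous_range"))
    }
    return(list(value = mean(rng), rule = "range_mean"))
  }
  v <- suppressWarnings(as.numeric(compact))
  if (is.na(v)) return(list(value = NA_real_, rule = "non_numeric"))
  list(value = v, rule = NA_character_)
}

#' Sanitize a raw clinical mutation table
#'
#' Applies, in order: (1) keep only Point/Polymorphism mutation types with
#' Missense effect; (2) drop signal-peptide or out-of-mature positions
#' (legacy position outside 1..2332); (3) drop records with any reported
#' activity above 100; (4) substitute bound markers (\code{"> 5"} to 5,
#' \code{"< 10"} to 10, \code{"< 11"} to 11, \code{"< 1"} to 0); (5) replace
#' ranges \code{"a to b"} by their midpoint, dropping ranges whose
#' endpoints fall in different severity bands (severe < 1, moderate 1-5,
#' mild > 5-40); (6) drop non-numeric leftovers (including other
#' \code{"< x"} markers, which are ambiguous diagnostics), records missing
#' activity, records whose two assay columns disagree, stop codons, and
#' ambiguous severity strings such as \code{"mild/moderate"}. Parsing is
#' whitespace- and non-breaking-space-tolerant. Every removed record is
#' logged once with the rule that removed it, so input count = output count
#' + exclusion count, and the operation is idempotent.
#'
#' @param raw data.frame with columns \code{mutation_type},
#'   \code{variant_effect}, \code{position_legacy}, \code{fviii_c_raw},
#'   \code{severity_reported}; optional \code{fviii_c_1st},
#'   \code{fviii_c_2st}, \code{protein_change}.
#' @return list with \code{records} (sanitized table, numeric
#'   \code{fviii_c_value} in [0, 100]), \code{exclusions} (data.frame:
#'   \code{row_id}, \code{rule}, \code{raw_value}) and
#'   \code{transformations} (kept records whose activity string was
#'   rewritten by a bound or range rule: \code{row_id}, \code{rule},
#'   \code{raw_value}, \code{new_value}).
#' @examples
#' raw <- data.frame(mutation_type = "Point", variant_effect = "Missense",
#'                   position_legacy = 100, fviii_c_raw = "10 to 24",
#'                   severity_reported = "mild")
#' sanitizeRecords(raw)$records$fviii_c_value  # 17
#' @export
sanitizeRecords <- function(raw) {
  need <- c("mutation_type", "variant_effect", "position_legacy",
            "fviii_c_raw", "severity_reported")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("missing schema column(s): ", paste(miss, collapse = ", "))
  n <- nrow(raw)
  rule <- rep(NA_character_, n)
  rawval <- as.character(raw$fviii_c_raw)

  # (1) mutation type / variant effect
  typeOk <- tolower(trimws(raw$mutation_type)) %in% c("point", "polymorphism") &
    tolower(trimws(raw$variant_effect)) == "missense"
  rule[!typeOk & is.na(rule)] <- "type_effect"

  # (2) position inside the mature protein
  pos <- suppressWarnings(as.integer(raw$position_legacy))
  posOk <- !is.na(pos) & pos >= 1 & pos <= 2332
  rule[!posOk & is.na(rule)] <- "position_out_of_mature"

  # (6, early detectable) stop codons
  if (!is.null(raw$protein_change)) {
    isStop <- grepl("(\\*|Ter|X)$", raw$protein_change)
    rule[isStop & is.na(rule)] <- "stop_codon"
  }

  # parse activity strings (applies rules 4 and 5 per record)
  parsed <- lapply(rawval, .parseActivity)
  value <- vapply(parsed, function(p) p$value, 0)
  prule <- vapply(parsed, function(p) p$rule, "")

  # (3) any assay above 100
  over <- rep(FALSE, n)
  for (col in c("fviii_c_1st", "fviii_c_2st")) {
    if (!is.null(raw[[col]])) {
      v <- vapply(lapply(as.character(raw[[col]]), .parseActivity),
                  function(p) p$value, 0)
      over <- over | (!is.na(v) & v > 100)
    }
  }
  over <- over | (!is.na(value) & value > 100)
  rule[over & is.na(rule)] <- "activity_above_100"

  # (6) parse failures
  dropParse <- prule %in% c("ambiguous_range", "non_numeric", "missing_activity")
  rule[dropParse & is.na(rule)] <- prule[dropParse & is.na(rule)]

  # (6) assay disagreement between the two FVIII:C columns
  if (!is.null(raw$fviii_c_1st) && !is.null(raw$fviii_c_2st)) {
    v1 <- vapply(lapply(as.character(raw$fviii_c_1st), .parseActivity),
                 function(p) p$value, 0)
    v2 <- vapply(lapply(as.character(raw$fviii_c_2st), .parseActivity),
                 function(p) p$value, 0)
    disagree <- !is.na(v1) & !is.na(v2) & abs(v1 - v2) > 1e-9
    rule[disagree & is.na(rule)] <- "assay_disagreement"
  }

  # (6) ambiguous severity
  sev <- tolower(trimws(as.character(raw$severity_reported)))
  sevOk <- sev %in% c("mild", "moderate", "severe")
  rule[!sevOk & is.na(rule)] <- "ambiguous_severity"

  keep <- is.na(rule)
  records <- raw[keep, , drop = FALSE]
  records$position_legacy <- pos[keep]
  records$fviii_c_value <- value[keep]
  records$fviii_c_raw <- as.character(value[keep])
  records$severity_reported <- sev[keep]
  rownames(records) <- NULL
  exclusions <- data.frame(row_id = which(!keep), rule = rule[!keep],
                           raw_value = rawval[!keep], stringsAsFactors = FALSE)
  transformed <- keep & !is.na(prule) & prule != "" &
    grepl("^(bound:|range_mean)", prule) &
    .normActivity(rawval) != as.character(value)
  transformations <- data.frame(row_id = which(transformed),
                                rule = prule[transformed],
                                raw_value = rawval[transformed],
                                new_value = value[transformed],
                                stringsAsFactors = FALSE)
  list(records = records, exclusions = exclusions,
       transformations = transformations)
}

#' Fisher's exact association between residue groups and reported mutations
#'
#' Builds the 2x2 table \{group A, group B\} x \{position has at least one
#' reported mutation, has none\} and tests it with the two-sided exact
#' hypergeometric test. The odds ratio is the sample cross-product (not the
#' conditional MLE), with \code{Inf} on zero cells.
#'
#' @param groupA,groupB disjoint, nonempty sets of positions (any atomic
#'   type comparable by \code{\%in\%}).
#' @param reportedPositions positions carrying at least one reported
#'   mutation.
#' @return data.frame row: the four counts, \code{odds_ratio},
#'   \code{p_value}, \code{test_name}.
#' @export
fisherAssociation <- function(groupA, groupB, reportedPositions) {
  stopifnot(length(groupA) > 0, length(groupB) > 0)
  if (length(intersect(groupA, groupB))) stop("groups must be disjoint")
  aRep <- sum(groupA %in% reportedPositions); aNo <- length(groupA) - aRep
  bRep <- sum(groupB %in% reportedPositions); bNo <- length(groupB) - bRep
  tab <- matrix(c(aRep, aNo, bRep, bNo), 2, 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("degenerate 2x2 margin; association untestable, p set to 1")
    p <- 1
  } else {
    p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  }
  or <- if (aNo * bRep == 0) {
    if (aRep * bNo == 0) NaN else Inf
  } else (aRep * bNo) / (aNo * bRep)
  data.frame(a_reported = aRep, a_none = aNo, b_reported = bRep, b_none = bNo,
             odds_ratio = or, p_value = min(1, p),
             test_name = "Fisher exact (two-sided)", stringsAsFactors = FALSE)
}

#' Convert legacy mature-protein numbering to HGVS numbering
#'
#' HGVS protein numbering counts the 19-residue signal peptide, so the HGVS
#' position is the legacy mature position plus 19 (e.g. Trp1942 in legacy
#' numbering is Trp1961 in HGVS).
#'
#' @param positionLegacy positive integer position(s) in mature numbering.
#' @return integer HGVS position(s).
#' @export
legacyToHgvs <- function(positionLegacy) {
  if (any(is.na(positionLegacy)) || any(positionLegacy < 1)) {
    stop("legacy positions must be positive")
  }
  as.integer(positionLegacy + 19L)
}
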