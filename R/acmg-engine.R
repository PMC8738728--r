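#' @include AllClasses.R
NULL

.strength_levels <- c("supporting", "moderate", "strong", "very_strong")

.base_strength <- c(PVS = "very_strong", PS = "strong", PM = "moderate",
                    PP = "supporting",
                    BA = "very_strong", BS = "strong", BP = "supporting")

# accepted modifier dialects, normalized to canonical tokens
.modifier_norm <- c(VS = "VS", STR = "STR", S = "STR", MOD = "MOD",
                    M = "MOD", SUP = "SUP", P = "SUP")

.modifier_strength <- c(VS = "very_strong", STR = "strong",
                        MOD = "moderate", SUP = "supporting")

.strength_points <- c(supporting = 1, moderate = 2, strong = 4,
                      very_strong = 8)

#' Parse an ACMG evidence token
#'
#' Tokens look like `PVS1`, `PM2_SUP` or `PS4_MOD`: a criterion label whose
#' prefix (PVS/PS/PM/PP, BA/BS/BP) fixes the base strength and direction,
#' with an optional strength modifier. Modifier dialects `_SUP`/`_P`,
#' `_MOD`/`_M`, `_STR`/`_S` and `_VS` are accepted and normalized.
#'
#' @param token evidence token, e.g. `"PVS1_STR"`.
#' @return an [EvidenceCode-class].
#' @examples
#' parseEvidence("PVS1_STR")  # base very_strong, effective strong
#' @export
parseEvidence <- function(token) {
  token <- trimws(token)
  m <- regmatches(token,
    regexec("^(PVS|PS|PM|PP|BA|BS|BP)([0-9]+)(?:_([A-Z]+))?$", token))[[1]]
  if (length(m) == 0L)
    stop("cannot parse evidence token '", token, "'")
  prefix <- m[2]
  modifier <- m[4]
  if (nzchar(modifier)) {
    if (!modifier %in% names(.modifier_norm))
      stop("unknown strength modifier '_", modifier, "' in '", token, "'")
    modifier <- .modifier_norm[[modifier]]
  } else modifier <- NA_character_
  base <- .base_strength[[prefix]]
  eff <- if (is.na(modifier)) base else .modifier_strength[[modifier]]
  new("EvidenceCode",
      label = paste0(prefix, m[3]), baseStrength = base,
      modifier = modifier, effectiveStrength = eff,
      direction = if (startsWith(prefix, "P")) "pathogenic" else "benign")
}

#' @rdname parseEvidence
#' @param tokens semicolon-separated token string, exactly the format of a
#'   variant table's evidence column (e.g. `"PVS1_STR; PM1_SUP; PM2_SUP"`).
#' @export
parseEvidenceList <- function(tokens) {
  parts <- trimws(strsplit(tokens, ";")[[1]])
  lapply(parts[nzchar(parts)], parseEvidence)
}

#' Format an EvidenceCode back to its token
#'
#' Inverse of [parseEvidence()] on canonical tokens.
#' @param code an `EvidenceCode`.
#' @export
formatEvidence <- function(code) {
  stopifnot(is(code, "EvidenceCode"))
  if (is.na(code@modifier)) code@label
  else paste0(code@label, "_", code@modifier)
}

#' Signed evidence points of a code
#'
#' Point scale: supporting = 1, moderate = 2, strong = 4, very strong = 8 at
#' the code's effective strength; benign-direction codes count negative.
#'
#' @param code an `EvidenceCode`.
#' @examples
#' pointsOf(parseEvidence("PVS1_STR"))  # 4
#' pointsOf(parseEvidence("BS1"))       # -4
#' @export
pointsOf <- function(code) {
  stopifnot(is(code, "EvidenceCode"))
  p <- .strength_points[[code@effectiveStrength]]
  if (code@direction == "benign") -p else p
}

.as_codes <- function(codes) {
  if (is.character(codes)) codes <- lapply(codes, parseEvidence)
  stopifnot(all(vapply(codes, is, logical(1), "EvidenceCode")))
  codes
}

#' Combine evidence codes with the point system
#'
#' Sums the signed points of all codes and maps the total to a five-tier
#' call: >= 10 pathogenic, 6..9 likely pathogenic, 0..5 uncertain,
#' -6..-1 likely benign, <= -7 benign.
#'
#' @param codes list of [EvidenceCode-class] objects or character tokens;
#'   may be empty (0 points, uncertain).
#' @return a [Classification-class] with the per-code point trace.
#' @examples
#' classifyPoints(c("PVS1_STR", "PM1_SUP", "PM2_SUP"))  # 6 -> likely_pathogenic
#' @export
classifyPoints <- function(codes) {
  codes <- .as_codes(codes)
  pts <- vapply(codes, pointsOf, numeric(1))
  total <- sum(pts)
  tier <- if (total >= 10) "pathogenic"
    else if (total >= 6) "likely_pathogenic"
    else if (total >= 0) "uncertain"
    else if (total >= -6) "likely_benign"
    else "benign"
  new("Classification", tier = tier, points = total,
      ruleTrace = data.frame(
        code = vapply(codes, formatEvidence, character(1)),
        points = pts, stringsAsFactors = FALSE),
      conflict = FALSE, combiner = "points")
}

#' Combine evidence codes with the published rule table
#'
#' Applies the original combining rules over counts of effective-strength
#' criteria (modifiers are mapped to their effective category first). When
#' both a pathogenic and a benign rule fire, the call is uncertain with the
#' conflict flag set.
#'
#' @inheritParams classifyPoints
#' @return a [Classification-class].
#' @examples
#' classifyRules(c("PVS1", "PS1"))          # pathogenic
#' classifyRules(c("PM2", "PM3", "PP3"))    # uncertain
#' @export
classifyRules <- function(codes) {
  codes <- .as_codes(codes)
  eff <- vapply(codes, slot, character(1), "effectiveStrength")
  dir <- vapply(codes, slot, character(1), "direction")
  labels <- vapply(codes, slot, character(1), "label")
  nPVS <- sum(dir == "pathogenic" & eff == "very_strong")
  nPS <- sum(dir == "pathogenic" & eff == "strong")
  nPM <- sum(dir == "pathogenic" & eff == "moderate")
  nPP <- sum(dir == "pathogenic" & eff == "supporting")
  standalone <- any(labels == "BA1" & vapply(codes, function(x)
    is.na(x@modifier), logical(1)))
  nBS <- sum(dir == "benign" & eff == "strong") +
    sum(dir == "benign" & eff == "very_strong" & labels != "BA1")
  nBP <- sum(dir == "benign" & eff %in% c("supporting", "moderate"))
  pathogenic <-
    (nPVS >= 1 && (nPS >= 1 || nPM >= 2 || (nPM >= 1 && nPP >= 1) ||
                     nPP >= 2)) ||
    nPS >= 2 ||
    (nPS == 1 && (nPM >= 3 || (nPM == 2 && nPP >= 2) ||
                    (nPM == 1 && nPP >= 4)))
  likely_pathogenic <-
    (nPVS >= 1 && nPM == 1) ||
    (nPS == 1 && nPM >= 1 && nPM <= 2) ||
    (nPS == 1 && nPP >= 2) ||
    nPM >= 3 ||
    (nPM == 2 && nPP >= 2) ||
    (nPM == 1 && nPP >= 4)
  benign <- standalone || nBS >= 2
  likely_benign <- (nBS == 1 && nBP >= 1) || nBP >= 2
  pathSide <- pathogenic || likely_pathogenic
  benSide <- benign || likely_benign
  conflict <- pathSide && benSide
  tier <- if (conflict) "uncertain"
    else if (pathogenic) "pathogenic"
    else if (likely_pathogenic) "likely_pathogenic"
    else if (benign) "benign"
    else if (likely_benign) "likely_benign"
    else "uncertain"
  new("Classification", tier = tier, points = 0,
      ruleTrace = data.frame(
        code = vapply(codes, formatEvidence, character(1)),
        points = vapply(codes, pointsOf, numeric(1)),
        stringsAsFactors = FALSE),
      conflict = conflict, combiner = "rules")
}

setMethod("show", "Classification", function(object) {
  cat("ACMG classification (", object@combiner, " combiner): ",
      object@tier, sep = "")
  if (object@combiner == "points") cat(" [", object@points, " points]", sep = "")
  if (object@conflict) cat(" [conflicting evidence]")
  cat("\n")
  if (nrow(object@ruleTrace))
    cat("  ", paste(sprintf("%s(%+g)", object@ruleTrace$code,
                            object@ruleTrace$points), collapse = " "), "\n",
        sep = "")
})

## Table I/O -----------------------------------------------------------------

#' Classify a variant evidence table
#'
#' Input: a TSV with a variant id column and a semicolon-separated evidence
#' token column. Output: one row per variant with points and the tiers from
#' both combiners.
#'
#' @param x data.frame with columns `variant` and `evidence`, or a TSV path.
#' @return data.frame with columns `variant`, `evidence`, `points`,
#'   `tier_points`, `tier_rules`, `conflict`.
#' @export
classifyEvidenceTable <- function(x) {
  if (is.character(x))
    x <- read.table(x, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("variant", "evidence") %in% names(x)))
  res <- lapply(x$evidence, function(ev) {
    codes <- parseEvidenceList(ev)
    pt <- classifyPoints(codes)
    rl <- classifyRules(codes)
    data.frame(points = pt@points, tier_points = pt@tier,
               tier_rules = rl@tier, conflict = rl@conflict,
               stringsAsFactors = FALSE)
  })
  cbind(x[, c("variant", "evidence")], do.call(rbind, res))
}
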