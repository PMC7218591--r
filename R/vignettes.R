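# Coded clinical vignettes: structured patient cases with a gold-standard
# 3-item differential, serialized as JSON lines (one vignette per line).

.strata <- c("high", "moderate", "low")

#' Construct a coded clinical vignette
#'
#' A vignette is a structured patient case: optional demographics, a
#' non-empty list of coded findings, a specificity stratum (`high`,
#' `moderate`, `low` — how characteristic the presentation is of the
#' underlying disease), and a gold-standard differential of one primary
#' plus two secondary diagnoses whose sureties sum to 100 (fewer than 3
#' items are tolerated only when the disease universe itself is smaller;
#' the interchange schema fixes the standard form at 3). Vignettes are
#' pre-coded: mapping free-text histories onto symptom codes is outside
#' this package's contract.
#'
#' @param id unique vignette identifier.
#' @param findings non-empty list of [finding()] objects.
#' @param stratum one of `"high"`, `"moderate"`, `"low"`.
#' @param gold a 3-item `ddx_differential` ([differential()]).
#' @param demographics optional named list with any of `age` (years),
#'   `sex` (`"female"`, `"male"`, `"other"`), `presentation_date`
#'   (ISO-8601 string; metadata only, never used computationally).
#' @return a `ddx_vignette`.
#' @export
clinical_vignette <- function(id, findings, stratum, gold,
                              demographics = list()) {
  .stop_if(!is.character(id) || length(id) != 1 || !nzchar(id),
           "vignette id must be a non-empty string")
  .stop_if(!stratum %in% .strata,
           sprintf("stratum must be one of %s", paste(.strata, collapse = ", ")))
  if (inherits(findings, "ddx_finding")) findings <- list(findings)
  .stop_if(length(findings) == 0, sprintf("vignette '%s' has no findings", id))
  ok <- vapply(findings, inherits, TRUE, what = "ddx_finding")
  .stop_if(!all(ok), "findings must be finding() objects")
  .stop_if(!inherits(gold, "ddx_differential"), "gold must be a differential()")
  .stop_if(nrow(gold) > 3L,
           sprintf("gold differential must have at most 3 items, got %d", nrow(gold)))
  if (!is.null(demographics$sex))
    .stop_if(!demographics$sex %in% c("female", "male", "other"),
             sprintf("unknown sex '%s'", demographics$sex))
  structure(list(id = id, demographics = demographics, findings = findings,
                 stratum = stratum, gold = gold),
            class = "ddx_vignette")
}

#' @export
print.ddx_vignette <- function(x, ...) {
  cat(sprintf("<ddx_vignette> %s [%s] %d finding(s); gold primary: %s\n",
              x$id, x$stratum, length(x$findings), x$gold$disease_id[1]))
  invisible(x)
}

#' Construct a vignette set
#'
#' @param vignettes list of `ddx_vignette` objects with unique ids.
#' @param label free-text provenance label.
#' @return a `ddx_vignette_set`.
#' @export
vignette_set <- function(vignettes = list(), label = "") {
  ok <- vapply(vignettes, inherits, TRUE, what = "ddx_vignette")
  .stop_if(!all(ok), "all elements must be ddx_vignette objects")
  ids <- vapply(vignettes, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop(ddx_error(sprintf("duplicate vignette id(s): %s",
                           paste(unique(ids[duplicated(ids)]), collapse = ", "))))
  structure(list(vignettes = vignettes, label = label),
            class = "ddx_vignette_set")
}

#' @export
print.ddx_vignette_set <- function(x, ...) {
  tab <- table(factor(vapply(x$vignettes, `[[`, "", "stratum"), levels = .strata))
  cat(sprintf("<ddx_vignette_set> %d vignette(s)%s | high %d, moderate %d, low %d\n",
              length(x$vignettes),
              if (nzchar(x$label)) paste0(" (", x$label, ")") else "",
              tab[["high"]], tab[["moderate"]], tab[["low"]]))
  invisible(x)
}

#' @export
length.ddx_vignette_set <- function(x) length(x$vignettes)

.vignette_to_list <- function(v) {
  dem <- v$demographics[!vapply(v$demographics, is.null, TRUE)]
  list(
    id = v$id,
    demographics = if (length(dem)) dem else stats::setNames(list(), character()),
    findings = lapply(v$findings, function(f)
      list(symptom_id = f$symptom_id, polarity = f$polarity)),
    stratum = v$stratum,
    gold = list(items = lapply(seq_len(nrow(v$gold)), function(i)
      list(disease_id = v$gold$disease_id[i],
           rank = v$gold$rank[i],
           surety = v$gold$surety[i])),
      k = nrow(v$gold))
  )
}

.vignette_from_list <- function(obj, where) {
  id <- .as_scalar_chr(.need(obj, "id", where), paste0(where, "/id"))
  fl <- .need(obj, "findings", where)
  findings <- lapply(seq_along(fl), function(i) {
    f <- fl[[i]]; w <- sprintf("%s/findings/%d", where, i - 1L)
    pol <- if (is.null(f$polarity)) "present"
           else .as_scalar_chr(f$polarity, paste0(w, "/polarity"))
    if (!pol %in% c("present", "absent"))
      stop(ddx_error(sprintf("polarity '%s' at %s/polarity", pol, w)))
    finding(.as_scalar_chr(.need(f, "symptom_id", w), paste0(w, "/symptom_id")), pol)
  })
  g <- .need(obj, "gold", where)
  items <- .need(g, "items", paste0(where, "/gold"))
  gid <- vapply(items, function(it) .as_scalar_chr(.need(it, "disease_id",
                paste0(where, "/gold/items")), "disease_id"), "")
  gsur <- vapply(items, function(it) .as_scalar_num(.need(it, "surety",
                 paste0(where, "/gold/items")), "surety"), 0)
  if (abs(sum(gsur) - 100) > 1e-9)
    stop(ddx_error(sprintf("gold surety values sum to %g, expected 100, at %s/gold",
                           sum(gsur), where)))
  dem <- obj$demographics
  dem <- if (is.null(dem)) list() else dem[!vapply(dem, is.null, TRUE)]
  clinical_vignette(
    id = id, findings = findings,
    stratum = .as_scalar_chr(.need(obj, "stratum", where), paste0(where, "/stratum")),
    gold = differential(gid, gsur),
    demographics = dem
  )
}

#' Read a vignette set from a JSON-lines file
#'
#' One vignette object per line (schema in `inst/schemas/`); every
#' structural error is reported with the offending line number. An empty
#' file yields an empty set with a warning.
#'
#' @param path JSON-lines file.
#' @param label provenance label for the returned set (defaults to the path).
#' @return a `ddx_vignette_set`.
#' @export
read_vignettes <- function(path, label = path) {
  .stop_if(!file.exists(path), sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warning(sprintf("empty vignette file: %s", path), call. = FALSE)
    return(vignette_set(list(), label = label))
  }
  vigs <- lapply(seq_along(lines), function(i) {
    obj <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
                    error = function(e) stop(ddx_error(
                      sprintf("line %d: malformed JSON: %s", i, conditionMessage(e)))))
    tryCatch(.vignette_from_list(obj, sprintf("line %d", i)),
             ddx_validation_error = function(e) stop(ddx_error(
               sprintf("line %d: %s", i, conditionMessage(e)))))
  })
  vignette_set(vigs, label = label)
}

#' Write a vignette set to a JSON-lines file
#'
#' Serialization is byte-stable: fixed key order, one compact JSON object
#' per line, so rewriting an unchanged set reproduces the file exactly and
#' [read_vignettes()] round-trips it.
#'
#' @param vs a `ddx_vignette_set`.
#' @param path output path.
#' @export
write_vignettes <- function(vs, path) {
  .stop_if(!inherits(vs, "ddx_vignette_set"), "expected a ddx_vignette_set")
  lines <- vapply(vs$vignettes, function(v)
    as.character(jsonlite::toJSON(.vignette_to_list(v), auto_unbox = TRUE,
                                  digits = NA)), "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Partition a vignette set by specificity stratum
#'
#' @param vs a `ddx_vignette_set`.
#' @return named list `high`, `moderate`, `low` of `ddx_vignette_set`s;
#'   within-stratum order is preserved and the union equals `vs`.
#' @export
stratify <- function(vs) {
  .stop_if(!inherits(vs, "ddx_vignette_set"), "expected a ddx_vignette_set")
  st <- vapply(vs$vignettes, `[[`, "", "stratum")
  out <- lapply(.strata, function(s)
    vignette_set(vs$vignettes[st == s],
                 label = sprintf("%s [%s]", vs$label, s)))
  stats::setNames(out, .strata)
}
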