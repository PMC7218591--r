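# Knowledge-base serialization. Two formats:
#   json — single document (schema in inst/schemas/knowledge_base.schema.json)
#   csv  — a directory holding entities.csv + weights.csv

.kb_guess_format <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
}

.need <- function(x, key, where) {
  if (is.null(x[[key]]))
    stop(ddx_error(sprintf("missing key '%s' at %s", key, where)))
  x[[key]]
}

.as_scalar_chr <- function(x, where) {
  if (!(is.character(x) || is.numeric(x)) || length(x) != 1)
    stop(ddx_error(sprintf("expected a string at %s", where)))
  as.character(x)
}

.as_scalar_num <- function(x, where) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x))
    stop(ddx_error(sprintf("expected a number at %s", where)))
  as.numeric(x)
}

#' Load a knowledge base from disk
#'
#' Reads and validates a knowledge base. JSON input is a single object with
#' keys `diseases`, `symptoms` and `weights` (see the schema shipped in
#' `inst/schemas/`); CSV input is a directory containing `entities.csv` and
#' `weights.csv`. Missing weight cells are filled with 0; priors are
#' normalized to sum to 1 when all are non-negative. Schema violations are
#' reported with a JSON-pointer-style path to the offending element.
#'
#' @param path file (json) or directory (csv).
#' @param format `"json"` or `"csv"`; guessed from the path when omitted.
#' @return a validated `ddx_kb`.
#' @seealso [save_knowledge_base()], [validate_knowledge_base()]
#' @export
load_knowledge_base <- function(path, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (format == "auto") format <- .kb_guess_format(path)
  if (!file.exists(path))
    stop(ddx_error(sprintf("no such file or directory: %s", path)))
  kb <- if (format == "json") .kb_from_json(path) else .kb_from_csv(path)
  .assert_valid_kb(kb)
}

.kb_from_json <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stop(ddx_error(
                    sprintf("malformed JSON in %s: %s", path, conditionMessage(e)))))
  dis <- .need(doc, "diseases", "/")
  sym <- .need(doc, "symptoms", "/")
  wts <- if (is.null(doc$weights)) list() else doc$weights

  empty_df <- function(...) data.frame(..., stringsAsFactors = FALSE)
  if (length(dis) == 0)
    stop(ddx_error("empty disease list at /diseases"))
  diseases <- do.call(rbind, lapply(seq_along(dis), function(i) {
    d <- dis[[i]]; w <- sprintf("/diseases/%d", i - 1L)
    data.frame(
      id    = .as_scalar_chr(.need(d, "id", w), paste0(w, "/id")),
      name  = .as_scalar_chr(.need(d, "name", w), paste0(w, "/name")),
      prior = if (is.null(d$prior)) NA_real_
              else .as_scalar_num(d$prior, paste0(w, "/prior")),
      stringsAsFactors = FALSE)
  }))
  symptoms <- if (length(sym) == 0) {
    empty_df(id = character(), name = character(), category = character())
  } else do.call(rbind, lapply(seq_along(sym), function(i) {
    s <- sym[[i]]; w <- sprintf("/symptoms/%d", i - 1L)
    data.frame(
      id       = .as_scalar_chr(.need(s, "id", w), paste0(w, "/id")),
      name     = .as_scalar_chr(.need(s, "name", w), paste0(w, "/name")),
      category = if (is.null(s$category)) "present_illness"
                 else .as_scalar_chr(s$category, paste0(w, "/category")),
      stringsAsFactors = FALSE)
  }))

  W <- matrix(0, nrow(symptoms), nrow(diseases),
              dimnames = list(symptoms$id, diseases$id))
  for (sid in names(wts)) {
    if (!sid %in% symptoms$id)
      stop(ddx_error(sprintf("undeclared symptom id at /weights/%s", sid)))
    row <- wts[[sid]]
    for (did in names(row)) {
      if (!did %in% diseases$id)
        stop(ddx_error(sprintf("undeclared disease id at /weights/%s/%s", sid, did)))
      v <- .as_scalar_num(row[[did]], sprintf("/weights/%s/%s", sid, did))
      if (v < 0 || v > 1)
        stop(ddx_error(sprintf("weight %.12g outside [0, 1] at /weights/%s/%s",
                               v, sid, did)))
      W[sid, did] <- v
    }
  }
  knowledge_base(diseases, symptoms, W)
}

.kb_from_csv <- function(path) {
  efile <- file.path(path, "entities.csv")
  wfile <- file.path(path, "weights.csv")
  .stop_if(!file.exists(efile), sprintf("missing %s", efile))
  .stop_if(!file.exists(wfile), sprintf("missing %s", wfile))
  ent <- utils::read.csv(efile, colClasses = "character",
                         fileEncoding = "UTF-8")
  need <- c("kind", "id", "name", "prior_or_category")
  .stop_if(!all(need %in% names(ent)),
           sprintf("entities.csv must have columns %s", paste(need, collapse = ", ")))
  d <- ent[ent$kind == "disease", , drop = FALSE]
  s <- ent[ent$kind == "symptom", , drop = FALSE]
  .stop_if(nrow(d) == 0, "entities.csv declares no diseases")
  diseases <- data.frame(id = d$id, name = d$name,
                         prior = suppressWarnings(as.numeric(d$prior_or_category)),
                         stringsAsFactors = FALSE)
  symptoms <- data.frame(id = s$id, name = s$name,
                         category = s$prior_or_category,
                         stringsAsFactors = FALSE)
  wm <- utils::read.csv(wfile, check.names = FALSE, fileEncoding = "UTF-8")
  .stop_if(names(wm)[1] != "symptom_id", "weights.csv first column must be symptom_id")
  W <- as.matrix(wm[, -1, drop = FALSE])
  rownames(W) <- wm$symptom_id
  storage.mode(W) <- "double"
  bad <- which(is.na(W) | W < 0 | W > 1, arr.ind = TRUE)
  if (nrow(bad))
    stop(ddx_error(sprintf("weight outside [0, 1] at /weights/%s/%s",
                           rownames(W)[bad[1, 1]], colnames(W)[bad[1, 2]])))
  knowledge_base(diseases, symptoms, W)
}

#' Save a knowledge base to disk
#'
#' Writes a knowledge base in either format such that
#' [load_knowledge_base()] reproduces it. The KB must validate cleanly;
#' nothing is written otherwise.
#'
#' @param kb a valid `ddx_kb`.
#' @param path output file (json) or directory (csv; created if absent).
#' @param format `"json"` or `"csv"`; guessed from `path` when omitted.
#' @export
save_knowledge_base <- function(kb, path, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (format == "auto") format <- .kb_guess_format(path)
  .assert_valid_kb(kb)
  if (format == "json") .kb_to_json(kb, path) else .kb_to_csv(kb, path)
  invisible(path)
}

.kb_to_json <- function(kb, path) {
  dis <- lapply(seq_len(nrow(kb$diseases)), function(i)
    list(id = kb$diseases$id[i], name = kb$diseases$name[i],
         prior = kb$diseases$prior[i]))
  sym <- lapply(seq_len(nrow(kb$symptoms)), function(i)
    list(id = kb$symptoms$id[i], name = kb$symptoms$name[i],
         category = kb$symptoms$category[i]))
  wts <- lapply(stats::setNames(kb$symptoms$id, kb$symptoms$id), function(sid) {
    row <- kb$weights[sid, ]
    as.list(row[row != 0])
  })
  wts <- wts[vapply(wts, length, 1L) > 0]
  doc <- list(diseases = dis, symptoms = sym, weights = wts)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(json, path, useBytes = TRUE)
}

.kb_to_csv <- function(kb, path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  ent <- rbind(
    data.frame(kind = "disease", id = kb$diseases$id, name = kb$diseases$name,
               prior_or_category = format(kb$diseases$prior, digits = 17,
                                          scientific = FALSE, trim = TRUE),
               stringsAsFactors = FALSE),
    data.frame(kind = "symptom", id = kb$symptoms$id, name = kb$symptoms$name,
               prior_or_category = kb$symptoms$category,
               stringsAsFactors = FALSE))
  utils::write.csv(ent, file.path(path, "entities.csv"), row.names = FALSE,
                   fileEncoding = "UTF-8")
  wm <- data.frame(symptom_id = rownames(kb$weights),
                   kb$weights, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(wm, file.path(path, "weights.csv"), row.names = FALSE,
                   fileEncoding = "UTF-8")
}
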