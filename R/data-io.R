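#' Read an overall-survival table
#'
#' Expects delimited text with patient, follow-up time and event columns
#' (names configurable). Patients appearing on more than one row are removed
#' entirely, not merged: repeated samples per patient are excluded from
#' survival analysis. Event codes `0`/`1`, `alive`/`dead` and
#' `LIVING`/`DECEASED` are accepted.
#'
#' @param path File path (TSV).
#' @param condition Condition name attached to the table.
#' @param col_patient,col_time,col_event Column names in the file.
#' @return A tibble of class `survival_table` with columns `patient_id`,
#'   `time` (days), `event` (1 = death observed, 0 = censored).
#' @export
read_survival_table <- function(path, condition = basename(path),
                                col_patient = "patient_id", col_time = "time",
                                col_event = "event") {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  need <- c(col_patient, col_time, col_event)
  if (!all(need %in% names(raw))) {
    stop_comod(paste0("expected columns: ", paste(setdiff(need, names(raw)), collapse = ", ")),
               "comod_parse_error")
  }
  survival_table(
    patient_id = raw[[col_patient]],
    time = suppressWarnings(as.numeric(raw[[col_time]])),
    event = raw[[col_event]],
    condition = condition
  )
}

#' Construct a survival table
#'
#' @param patient_id Character vector of patient IDs.
#' @param time Non-negative follow-up times (days).
#' @param event Event indicator; `0`/`1` or alive/dead aliases.
#' @param condition Condition name.
#' @return A `survival_table` tibble; patients with repeated rows dropped.
#' @export
survival_table <- function(patient_id, time, event, condition = "condition") {
  if (anyNA(time)) stop_comod("non-numeric follow-up time", "comod_parse_error")
  if (any(time < 0)) stop_comod("negative follow-up time", "comod_validation_error")
  ev_chr <- tolower(as.character(event))
  map <- c("0" = 0, "1" = 1, "alive" = 0, "dead" = 1, "living" = 0, "deceased" = 1)
  if (!all(ev_chr %in% names(map))) {
    bad <- unique(ev_chr[!ev_chr %in% names(map)])
    stop_comod(paste0("unrecognized event codes: ", paste(head(bad, 5), collapse = ", ")),
               "comod_parse_error")
  }
  out <- tibble(patient_id = as.character(patient_id), time = as.numeric(time),
                event = unname(map[ev_chr]))
  dup <- unique(out$patient_id[duplicated(out$patient_id)])
  out <- out[!out$patient_id %in% dup, , drop = FALSE]
  attr(out, "condition") <- condition
  attr(out, "n_dropped_repeated") <- length(dup)
  class(out) <- c("survival_table", class(out))
  out
}

#' Read an undirected gene-gene edge list
#'
#' Two-column TSV (optionally a third annotation column). Self-loops are
#' dropped and duplicate undirected pairs collapsed.
#'
#' @param path File path.
#' @return Tibble with columns `from`, `to` and optionally `annotation`.
#' @export
read_edge_list <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(raw) < 2L) stop_comod("edge list needs two columns", "comod_parse_error")
  edges <- tibble(from = raw[[1]], to = raw[[2]])
  if (ncol(raw) >= 3L) edges$annotation <- raw[[3]]
  edge_list(edges)
}

#' Canonicalize an edge list
#'
#' @param edges Data frame with columns `from`, `to` (plus optional
#'   annotation).
#' @return Tibble with self-loops removed and undirected duplicates collapsed.
#' @export
edge_list <- function(edges) {
  edges <- as_tibble(edges)
  edges <- edges[edges$from != edges$to, , drop = FALSE]
  key <- ifelse(edges$from < edges$to,
                paste(edges$from, edges$to, sep = "\r"),
                paste(edges$to, edges$from, sep = "\r"))
  edges <- edges[!duplicated(key), , drop = FALSE]
  edges
}

#' Read a gene-ID mapping table
#'
#' Two-column TSV of `source_id` to `canonical_id`. A source ID may map to at
#' most one canonical ID; several source IDs may share one canonical ID
#' (redundancy, resolved later by [map_and_dedupe()]).
#'
#' @param path File path.
#' @return Tibble with columns `source_id`, `canonical_id`.
#' @export
read_id_map <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(raw) < 2L) stop_comod("ID map needs two columns", "comod_parse_error")
  out <- tibble(source_id = raw[[1]], canonical_id = raw[[2]])
  if (anyDuplicated(out$source_id)) {
    stop_comod("a source ID maps to more than one canonical ID", "comod_validation_error")
  }
  out
}
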