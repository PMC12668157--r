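#' Parse a structured HTAN-style identifier
#'
#' Consortium identifiers have the form `HTA<center>_<participant>` for
#' participants and `HTA<center>_<participant>_<suffix>` for biospecimens
#' and files, so the participant prefix is always recoverable from any
#' deeper id (e.g. `HTA13_1_101` belongs to participant `HTA13_1` at
#' center `HTA13`).
#'
#' @param id_text A single identifier string.
#' @return A list with `center_id` (e.g. `"HTA13"`), `participant_id`
#'   (e.g. `"HTA13_1"`), and `local_suffix` (`NA` for a bare participant
#'   id).
#' @export
#' @examples
#' parse_htan_id("HTA13_1_101")
parse_htan_id <- function(id_text) {
  stopifnot(is.character(id_text), length(id_text) == 1L)
  m <- regmatches(id_text,
                  regexec("^HTA([0-9]+)_([0-9]+)(?:_(.+))?$", id_text))[[1L]]
  if (!length(m)) {
    # report the first character at which the text leaves the id grammar
    ok_prefix <- function(p) {
      grepl("^H$|^HT$|^HTA[0-9]*$|^HTA[0-9]+_[0-9]*$|^HTA[0-9]+_[0-9]+_.*$",
            p)
    }
    pos <- 1L
    for (i in seq_len(nchar(id_text))) {
      if (!ok_prefix(substr(id_text, 1L, i))) { pos <- i; break }
      pos <- i + 1L
    }
    stop(sprintf("malformed HTAN id '%s': unexpected content at position %d",
                 id_text, pos), call. = FALSE)
  }
  list(center_id = paste0("HTA", m[2L]),
       participant_id = paste0("HTA", m[2L], "_", m[3L]),
       local_suffix = if (nzchar(m[4L])) m[4L] else NA_character_)
}

#' Build a provenance graph over participants, biospecimens and files
#'
#' The provenance graph links every derived file back through its
#' biospecimen(s) to one participant, mirroring consortium identifier
#' lineage tables. Edges run child -> parent.
#'
#' @param nodes data.frame with columns `htan_id`, `node_kind`
#'   (`participant`/`biospecimen`/`file`), `parent_ids` (`;`-separated
#'   string, empty for roots), plus any attribute columns (`assay_type`,
#'   `level`, `center`, `file_format`, `repository_file_id`, `drs_uri`,
#'   `data_release`, ...).
#' @return An object of class `provenance_graph`.
#' @export
provenance_graph <- function(nodes) {
  need <- c("htan_id", "node_kind", "parent_ids")
  miss <- setdiff(need, names(nodes))
  if (length(miss)) {
    stop("`nodes` is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(nodes$htan_id)) {
    stop("duplicate htan_id values in provenance nodes", call. = FALSE)
  }
  bad_kind <- setdiff(unique(nodes$node_kind),
                      c("participant", "biospecimen", "file"))
  if (length(bad_kind)) {
    stop("unknown node_kind value(s): ", paste(bad_kind, collapse = ", "),
         call. = FALSE)
  }
  plist <- strsplit(ifelse(is.na(nodes$parent_ids), "", nodes$parent_ids),
                    ";", fixed = TRUE)
  plist <- lapply(plist, function(p) trimws(p[nzchar(trimws(p))]))
  parents <- unlist(plist, use.names = FALSE)
  unknown <- setdiff(parents, nodes$htan_id)
  if (length(unknown)) {
    stop("parent id(s) not present as nodes: ",
         paste(head(unknown, 5L), collapse = ", "), call. = FALSE)
  }
  edges <- data.frame(
    from = rep(nodes$htan_id, lengths(plist)),
    to = parents
  )
  g <- igraph::graph_from_data_frame(
    edges, directed = TRUE, vertices = data.frame(name = nodes$htan_id))
  if (!igraph::is_dag(g)) {
    stop("provenance graph contains a cycle", call. = FALSE)
  }
  obj <- structure(list(nodes = nodes, igraph = g),
                   class = "provenance_graph")
  # every file must descend from >= 1 biospecimen and exactly 1 participant
  kind <- setNames(nodes$node_kind, nodes$htan_id)
  for (f in nodes$htan_id[nodes$node_kind == "file"]) {
    anc <- lineage(obj, f, "ancestors")
    if (sum(kind[anc] == "biospecimen") < 1L ||
        sum(kind[anc] == "participant") != 1L) {
      stop(sprintf(paste0("file '%s' must have at least one biospecimen ",
                          "ancestor and exactly one participant ancestor"),
                   f), call. = FALSE)
    }
  }
  obj
}

#' @export
print.provenance_graph <- function(x, ...) {
  tab <- table(x$nodes$node_kind)
  cat(sprintf("<provenance_graph> %s\n",
              paste(sprintf("%d %s", as.integer(tab), names(tab)),
                    collapse = ", ")))
  invisible(x)
}

#' Transitive lineage of a provenance node
#'
#' All identifiers reachable from `id` along parent edges (`ancestors`:
#' the biospecimens and participant a file derives from) or against them
#' (`descendants`: everything derived from a participant or biospecimen).
#' The query id itself is excluded.
#'
#' @param graph A [provenance_graph()].
#' @param id An `htan_id` present in the graph.
#' @param direction `"ancestors"` or `"descendants"`.
#' @return Sorted character vector of reachable `htan_id`s.
#' @export
lineage <- function(graph, id, direction = c("ancestors", "descendants")) {
  stopifnot(inherits(graph, "provenance_graph"))
  direction <- match.arg(direction)
  if (!id %in% graph$nodes$htan_id) {
    stop(sprintf("id '%s' is not in the provenance graph", id),
         call. = FALSE)
  }
  mode <- if (direction == "ancestors") "out" else "in"
  reach <- igraph::subcomponent(graph$igraph, id, mode = mode)
  sort(setdiff(names(reach), id))
}

# controlled-vocabulary normalization: trim, squeeze whitespace, casefold
.norm_term <- function(x) {
  tolower(gsub("[[:space:]]+", " ", trimws(as.character(x))))
}

#' Select participants whose tissue of origin rolls up to an organ
#'
#' Clinical tables record fine-grained tissue-or-organ-of-origin terms; a
#' roll-up map to broader whole-organ categories supports organ-level
#' cohort discovery (e.g. every breast participant regardless of the
#' specific breast subsite term). Term matching is exact after whitespace
#' squeezing and case folding; records whose term is absent from the map
#' are skipped with a warning.
#'
#' @param clinical data.frame with `participant_id` and
#'   `tissue_or_organ_of_origin`.
#' @param organ_map Named character vector: tissue term -> organ category.
#' @param organ Requested organ category (must occur in the map's range).
#' @return Sorted character vector of participant ids.
#' @export
organ_cohort <- function(clinical, organ_map, organ) {
  need <- c("participant_id", "tissue_or_organ_of_origin")
  miss <- setdiff(need, names(clinical))
  if (length(miss)) {
    stop("`clinical` is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  map <- setNames(.norm_term(organ_map), .norm_term(names(organ_map)))
  if (!.norm_term(organ) %in% map) {
    stop(sprintf("organ '%s' is not a category of the organ map", organ),
         call. = FALSE)
  }
  term <- .norm_term(clinical$tissue_or_organ_of_origin)
  unmapped <- !(term %in% names(map))
  if (any(unmapped)) {
    warning(sprintf("%d record(s) with tissue term(s) absent from the organ map were skipped (e.g. '%s')",
                    sum(unmapped),
                    clinical$tissue_or_organ_of_origin[unmapped][1L]),
            call. = FALSE)
  }
  hit <- !unmapped & map[term] == .norm_term(organ)
  sort(unique(as.character(clinical$participant_id[hit])))
}

#' Canonicalize an ICD-O-3 morphology code
#'
#' Morphology codes arrive in several dialects across centers. Accepted
#' forms are the canonical `dddd/d` (passed through), and five contiguous
#' digits with or without a leading `M` (`M82110` or `82110`, canonicalized
#' by inserting `/` before the final behavior digit). Anything else is
#' rejected as `NA` rather than raising, so tables can be scrubbed with a
#' report of rejects.
#'
#' @param code_text Character vector of raw code strings.
#' @return Character vector of canonical codes, `NA` where rejected.
#' @export
#' @examples
#' canonicalize_morphology(c("M82110", "8220/0", "82-x"))
canonicalize_morphology <- function(code_text) {
  x <- trimws(as.character(code_text))
  out <- rep(NA_character_, length(x))
  std <- grepl("^[0-9]{4}/[0-9]$", x)
  out[std] <- x[std]
  five <- !std & grepl("^M?[0-9]{5}$", x)
  y <- sub("^M", "", x[five])
  out[five] <- paste0(substr(y, 1L, 4L), "/", substr(y, 5L, 5L))
  out
}

#' Configuration for the precancer union query
#'
#' The four criteria of [precancer_union()], with the consortium's
#' documented value sets as defaults: (age-sentinel) age at diagnosis
#' equal to a sentinel at a precancer-designated center, with primary
#' diagnosis "Not Reported"; (diagnosis) an explicitly precancerous
#' primary diagnosis; (tissue-type) a premalignant biospecimen tumor
#' tissue type; (morphology) a premalignant ICD-O-3 morphology code after
#' canonicalization.
#'
#' @param precancer_centers Character vector of center ids (e.g.
#'   `"HTA1"`) designated as precancer atlases.
#' @param age_sentinel Sentinel value of `age_at_diagnosis` marking the
#'   absence of a cancer diagnosis (default 0).
#' @param require_not_reported If `TRUE` (default) the age-sentinel
#'   criterion additionally requires `primary_diagnosis == "Not
#'   Reported"`.
#' @param diagnosis_values,tissue_type_values,morphology_codes Controlled
#'   value sets for the remaining criteria.
#' @return A list of class `precancer_config`.
#' @export
precancer_config <- function(
    precancer_centers,
    age_sentinel = 0,
    require_not_reported = TRUE,
    diagnosis_values = c("Ductal Carcinoma in situ",
                         "Familial Adenomatous Polyposis"),
    tissue_type_values = c("Premalignant", "Atypia - hyperplasia",
                           "Premalignant - in situ"),
    morphology_codes = c("8211/0", "8213/0", "8263/0", "8220/0")) {
  structure(list(precancer_centers = precancer_centers,
                 age_sentinel = age_sentinel,
                 require_not_reported = isTRUE(require_not_reported),
                 diagnosis_values = diagnosis_values,
                 tissue_type_values = tissue_type_values,
                 morphology_codes = morphology_codes),
            class = "precancer_config")
}

#' Precancer cohort by a union of clinical and biospecimen queries
#'
#' No single field identifies precancer cases, so the cohort is the union
#' of four queries: (1) participants at precancer-designated centers
#' whose age at diagnosis carries the no-cancer sentinel (and, by
#' default, primary diagnosis "Not Reported"); (2) participants with an
#' explicitly precancerous primary diagnosis; (3) participants with a
#' biospecimen whose tumor tissue type is premalignant; (4) participants
#' with a biospecimen whose canonicalized morphology code is in the
#' premalignant set. All value matching is exact after whitespace and
#' case normalization.
#'
#' @param clinical data.frame with `participant_id`, `center`,
#'   `age_at_diagnosis`, `primary_diagnosis`.
#' @param biospecimens data.frame with `biospecimen_id`,
#'   `participant_id`, `tumor_tissue_type`,
#'   `histologic_morphology_code`.
#' @param config A [precancer_config()].
#' @return data.frame with one row per cohort participant (deduplicated,
#'   sorted by id): `participant_id` and logical flags
#'   `by_age_sentinel`, `by_diagnosis`, `by_tissue_type`,
#'   `by_morphology` (biospecimen-level flags are ORed up to the
#'   participant). The biospecimen-granularity hits are attached as
#'   attribute `"biospecimen_hits"`.
#' @export
precancer_union <- function(clinical, biospecimens, config) {
  stopifnot(inherits(config, "precancer_config"))
  cneed <- c("participant_id", "center", "age_at_diagnosis",
             "primary_diagnosis")
  bneed <- c("biospecimen_id", "participant_id", "tumor_tissue_type",
             "histologic_morphology_code")
  cmiss <- setdiff(cneed, names(clinical))
  bmiss <- setdiff(bneed, names(biospecimens))
  if (length(cmiss) || length(bmiss)) {
    stop("missing required field(s): ",
         paste(c(cmiss, bmiss), collapse = ", "), call. = FALSE)
  }

  age_hit <- clinical$age_at_diagnosis == config$age_sentinel &
    .norm_term(clinical$center) %in% .norm_term(config$precancer_centers)
  if (config$require_not_reported) {
    age_hit <- age_hit &
      .norm_term(clinical$primary_diagnosis) == .norm_term("Not Reported")
  }
  diag_hit <- .norm_term(clinical$primary_diagnosis) %in%
    .norm_term(config$diagnosis_values)

  tt_hit <- .norm_term(biospecimens$tumor_tissue_type) %in%
    .norm_term(config$tissue_type_values)
  morph_hit <- canonicalize_morphology(
    biospecimens$histologic_morphology_code) %in% config$morphology_codes

  bhits <- data.frame(
    biospecimen_id = as.character(biospecimens$biospecimen_id),
    participant_id = as.character(biospecimens$participant_id),
    by_tissue_type = tt_hit, by_morphology = morph_hit
  )[tt_hit | morph_hit, , drop = FALSE]
  rownames(bhits) <- NULL

  ids <- sort(unique(c(
    as.character(clinical$participant_id[age_hit | diag_hit]),
    bhits$participant_id)))
  a <- setNames(rep(FALSE, length(ids)), ids)
  b <- a; cc <- a; d <- a
  a[as.character(clinical$participant_id[age_hit])] <- TRUE
  b[as.character(clinical$participant_id[diag_hit])] <- TRUE
  cc[unique(bhits$participant_id[bhits$by_tissue_type])] <- TRUE
  d[unique(bhits$participant_id[bhits$by_morphology])] <- TRUE

  out <- data.frame(participant_id = ids, by_age_sentinel = unname(a),
                    by_diagnosis = unname(b), by_tissue_type = unname(cc),
                    by_morphology = unname(d))
  attr(out, "biospecimen_hits") <- bhits
  out
}

#' Biospecimens assayed with two imaging modalities
#'
#' Cross-modal cohort construction: keeps biospecimens that, within a
#' center, have at least one released file of each of two assay types
#' (e.g. both H&E and MxIF). Files with a null/empty `data_release` are
#' ignored, matching the released-data-only convention.
#'
#' @param file_metadata data.frame with `center`,
#'   `parent_biospecimen_id`, `assay_type`, `data_release` (plus any file
#'   columns, which can be re-joined on `parent_biospecimen_id`).
#' @param modality_a,modality_b Assay-type names; both must occur among
#'   the table's `assay_type` values.
#' @return Sorted character vector of biospecimen ids having both
#'   modalities.
#' @export
cross_modal_match <- function(file_metadata, modality_a, modality_b) {
  need <- c("center", "parent_biospecimen_id", "assay_type", "data_release")
  miss <- setdiff(need, names(file_metadata))
  if (length(miss)) {
    stop("`file_metadata` is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  known <- unique(.norm_term(file_metadata$assay_type))
  for (m in c(modality_a, modality_b)) {
    if (!.norm_term(m) %in% known) {
      stop(sprintf("unknown modality '%s'; assay types present: %s", m,
                   paste(sort(unique(file_metadata$assay_type)),
                         collapse = ", ")), call. = FALSE)
    }
  }
  rel <- !is.na(file_metadata$data_release) &
    nzchar(trimws(as.character(file_metadata$data_release)))
  sub <- file_metadata[rel, , drop = FALSE]
  at <- .norm_term(sub$assay_type)
  key <- paste(.norm_term(sub$center), sub$parent_biospecimen_id, sep = "\r")
  has_a <- unique(key[at == .norm_term(modality_a)])
  has_b <- unique(key[at == .norm_term(modality_b)])
  both <- intersect(has_a, has_b)
  sort(unique(sub$parent_biospecimen_id[key %in% both]))
}

#' Build a download manifest for a set of files
#'
#' Resolves file nodes in the provenance graph to manifest rows carrying
#' their DRS locator (`drs://<prefix>:<object-id>`), center, assay type
#' and processing level. Files that are missing or carry a malformed DRS
#' URI are reported in a rejects table rather than silently dropped.
#'
#' @param graph A [provenance_graph()] whose file nodes carry `drs_uri`
#'   (and optionally `center`, `assay_type`, `level`) attributes.
#' @param cohort_file_ids Character vector of file `htan_id`s.
#' @return A list of class `drs_manifest`: `manifest` (data.frame sorted
#'   by file id: `htan_id`, `drs_uri`, `center`, `assay_type`, `level`)
#'   and `rejects` (data.frame `htan_id`, `reason`).
#' @export
build_manifest <- function(graph, cohort_file_ids) {
  stopifnot(inherits(graph, "provenance_graph"))
  nodes <- graph$nodes
  ids <- as.character(cohort_file_ids)
  get_attr <- function(col, idx) {
    if (col %in% names(nodes)) as.character(nodes[[col]][idx])
    else rep(NA_character_, length(idx))
  }
  idx <- match(ids, nodes$htan_id)
  reason <- rep(NA_character_, length(ids))
  reason[is.na(idx)] <- "not in provenance graph"
  isfile <- !is.na(idx) & nodes$node_kind[idx] == "file"
  reason[!is.na(idx) & !isfile] <- "not a file node"
  uri <- get_attr("drs_uri", idx)
  no_uri <- isfile & (is.na(uri) | !nzchar(uri))
  reason[no_uri] <- "missing drs_uri"
  bad_uri <- isfile & !no_uri & !grepl("^drs://[^:/[:space:]]+:[^[:space:]]+$", uri)
  reason[bad_uri] <- "malformed drs_uri"
  ok <- is.na(reason)
  manifest <- data.frame(htan_id = ids[ok], drs_uri = uri[ok],
                         center = get_attr("center", idx[ok]),
                         assay_type = get_attr("assay_type", idx[ok]),
                         level = get_attr("level", idx[ok]))
  manifest <- manifest[order(manifest$htan_id), , drop = FALSE]
  rownames(manifest) <- NULL
  rejects <- data.frame(htan_id = ids[!ok], reason = reason[!ok])
  rownames(rejects) <- NULL
  structure(list(manifest = manifest, rejects = rejects),
            class = "drs_manifest")
}

#' @export
print.drs_manifest <- function(x, ...) {
  cat(sprintf("<drs_manifest> %d file(s), %d reject(s)\n",
              nrow(x$manifest), nrow(x$rejects)))
  invisible(x)
}
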