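# Seeded generators for every input schema the analysis modules consume,
# with planted ground truth. One root seed streams per-table sub-seeds so
# extending a scenario never perturbs earlier tables.

.sub_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Default log-normal marker-intensity model
#'
#' Imaging marker intensities are nonnegative and right-skewed; a
#' log-normal per phenotype captures that shape. For each marker the
#' model gives `(meanlog, sdlog)` per phenotype plus a `.default` used
#' for every other phenotype. The default model separates a `Tumor`
#' phenotype on a keratin-like marker roughly one decade above
#' background, with overlapping tails.
#'
#' @return A named list usable as the `markers` field of
#'   [spatial_scenario()].
#' @export
default_marker_model <- function() {
  list(
    Keratin_570_cellRingMask = list(
      Tumor = c(meanlog = log(600), sdlog = 0.35),
      .default = c(meanlog = log(60), sdlog = 0.5)
    ),
    CD45 = list(
      Immune = c(meanlog = log(400), sdlog = 0.35),
      .default = c(meanlog = log(50), sdlog = 0.5)
    )
  )
}

#' Describe a synthetic spatial cell scenario
#'
#' Defines a planted spatial ground truth: Gaussian blobs of cells of
#' given phenotype (isotropic spread, truncated to the frame by
#' resampling) over a uniform background, with per-phenotype log-normal
#' marker intensities. The seed fixes all randomness.
#'
#' @param frame An [image_frame()].
#' @param blobs data.frame with columns `x`, `y` (blob centre, px),
#'   `spread` (Gaussian sd, px), `n` (>= 1 cells) and `phenotype`.
#'   Centres must lie inside the frame.
#' @param n_background Number of uniform background cells (default 0).
#' @param background_phenotype Phenotype of background cells.
#' @param markers Marker model (see [default_marker_model()]).
#' @param seed Root seed; identical seeds give identical tables.
#' @return A list of class `spatial_scenario`.
#' @export
spatial_scenario <- function(frame, blobs, n_background = 0,
                             background_phenotype = "Other",
                             markers = default_marker_model(),
                             seed = 1L) {
  stopifnot(inherits(frame, "image_frame"))
  need <- c("x", "y", "spread", "n", "phenotype")
  miss <- setdiff(need, names(blobs))
  if (length(miss)) {
    stop("`blobs` is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  inside <- blobs$x >= 0 & blobs$x <= frame$width_px &
    blobs$y >= 0 & blobs$y <= frame$height_px
  if (!all(inside)) {
    stop("blob centre(s) outside the image frame: rows ",
         paste(which(!inside), collapse = ", "), call. = FALSE)
  }
  if (any(blobs$n < 1) || any(blobs$spread <= 0)) {
    stop("each blob needs n >= 1 and spread > 0", call. = FALSE)
  }
  structure(list(frame = frame, blobs = blobs,
                 n_background = n_background,
                 background_phenotype = background_phenotype,
                 markers = markers, seed = as.integer(seed)),
            class = "spatial_scenario")
}

# draw n truncated-Gaussian coordinates inside [0, hi] by resampling
.rnorm_trunc <- function(n, mean, sd, hi) {
  out <- rnorm(n, mean, sd)
  bad <- which(out < 0 | out > hi)
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < 0 | out[bad] > hi]
  }
  out
}

#' Generate a synthetic cell table with planted phenotypes
#'
#' Draws cell centroids per the scenario's blob plan plus uniform
#' background, and marker intensities from the per-phenotype log-normal
#' model. Deterministic under the scenario seed.
#'
#' @param scenario A [spatial_scenario()].
#' @return A list: `cells` (cell table with `cell_id`, `x_centroid`,
#'   `y_centroid` and one column per marker) and `truth` (data.frame
#'   `cell_id`, `phenotype`, `blob` — `NA` for background cells).
#' @export
gen_spatial_cells <- function(scenario) {
  stopifnot(inherits(scenario, "spatial_scenario"))
  seeds <- .sub_seeds(scenario$seed, 2L)
  fr <- scenario$frame
  bl <- scenario$blobs

  set.seed(seeds[1L])
  xs <- ys <- numeric(0)
  phen <- character(0)
  blob <- integer(0)
  for (b in seq_len(nrow(bl))) {
    xs <- c(xs, .rnorm_trunc(bl$n[b], bl$x[b], bl$spread[b], fr$width_px))
    ys <- c(ys, .rnorm_trunc(bl$n[b], bl$y[b], bl$spread[b], fr$height_px))
    phen <- c(phen, rep(as.character(bl$phenotype[b]), bl$n[b]))
    blob <- c(blob, rep(b, bl$n[b]))
  }
  if (scenario$n_background > 0) {
    nb <- scenario$n_background
    xs <- c(xs, runif(nb, 0, fr$width_px))
    ys <- c(ys, runif(nb, 0, fr$height_px))
    phen <- c(phen, rep(scenario$background_phenotype, nb))
    blob <- c(blob, rep(NA_integer_, nb))
  }
  n <- length(xs)
  ids <- sprintf("cell_%05d", seq_len(n))

  set.seed(seeds[2L])
  cells <- data.frame(cell_id = ids, x_centroid = xs, y_centroid = ys)
  for (mk in names(scenario$markers)) {
    model <- scenario$markers[[mk]]
    par <- lapply(phen, function(p) {
      if (!is.null(model[[p]])) model[[p]] else model[[".default"]]
    })
    ml <- vapply(par, `[[`, numeric(1), "meanlog")
    sl <- vapply(par, `[[`, numeric(1), "sdlog")
    cells[[mk]] <- rlnorm(n, ml, sl)
  }
  list(cells = cells,
       truth = data.frame(cell_id = ids, phenotype = phen, blob = blob))
}

#' Describe a synthetic clinical/biospecimen/file metadata scenario
#'
#' Plants a precancer cohort by criterion-overlap cell: `precancer` is a
#' named count vector whose names are subsets of the letters `A`
#' (age-sentinel case at a precancer center), `B` (precancerous primary
#' diagnosis), `C` (premalignant biospecimen tissue type), `D`
#' (premalignant morphology code) plus `"none"` for non-precancer
#' participants — e.g. `c(A = 7, B = 5, AB = 3, none = 10)`. Each
#' participant receives two biospecimens (the first carries any planted
#' C/D values) and, per the `modalities` plan, imaging files:
#' `both` / `a_only` / `b_only` / `neither` released-file combinations,
#' and `both_null_release` biospecimens holding both modalities but no
#' data release (so they must not match).
#'
#' @param precancer Named nonnegative integer counts (see above).
#' @param modalities Named counts over biospecimens; the plan is
#'   truncated to the number of generated biospecimens.
#' @param modality_a,modality_b Assay-type names (default `H&E`, `MxIF`).
#' @param precancer_centers,other_centers Center id pools.
#' @param seed Root seed.
#' @return A list of class `cohort_scenario`.
#' @export
cohort_scenario <- function(precancer = c(A = 5, B = 5, C = 5, D = 5,
                                          none = 10),
                            modalities = c(both = 4, a_only = 4,
                                           b_only = 4, neither = 4,
                                           both_null_release = 2),
                            modality_a = "H&E", modality_b = "MxIF",
                            precancer_centers = c("HTA1", "HTA2"),
                            other_centers = c("HTA6", "HTA7"),
                            seed = 1L) {
  if (any(precancer < 0) || any(modalities < 0)) {
    stop("counts must be nonnegative", call. = FALSE)
  }
  combos <- names(precancer)
  ok <- combos == "none" | grepl("^A?B?C?D?$", combos) & nzchar(combos)
  if (is.null(combos) || !all(ok)) {
    stop("`precancer` names must be subsets of 'ABCD' (in order) or 'none'",
         call. = FALSE)
  }
  mok <- c("both", "a_only", "b_only", "neither", "both_null_release")
  if (is.null(names(modalities)) || !all(names(modalities) %in% mok)) {
    stop("`modalities` names must be among: ", paste(mok, collapse = ", "),
         call. = FALSE)
  }
  structure(list(precancer = precancer, modalities = modalities,
                 modality_a = modality_a, modality_b = modality_b,
                 precancer_centers = precancer_centers,
                 other_centers = other_centers, seed = as.integer(seed)),
            class = "cohort_scenario")
}

#' Generate synthetic clinical, biospecimen and file metadata
#'
#' Materializes a [cohort_scenario()] into the three metadata tables the
#' cohort operations consume, a provenance node table, and the planted
#' truth sets. Deterministic under the scenario seed.
#'
#' Planted values: criterion A participants get the age sentinel 0, a
#' precancer-designated center and primary diagnosis "Not Reported";
#' criterion B draws from the precancerous diagnosis set; criterion C/D
#' biospecimens draw from the premalignant tissue-type set and the
#' morphology codes (alternating `Mddddd` and `dddd/d` dialects to
#' exercise canonicalization). Non-flagged participants get plausible
#' invasive-cancer values.
#'
#' @param scenario A [cohort_scenario()].
#' @return A list: `clinical`, `biospecimens`, `file_metadata` (one row
#'   per file), `nodes` (for [provenance_graph()]), `truth` (list with
#'   `precancer` — data.frame of planted participant flags — and
#'   `cross_modal` — biospecimen ids planted with both released
#'   modalities), and `config` (a matching [precancer_config()]).
#' @export
gen_metadata <- function(scenario) {
  stopifnot(inherits(scenario, "cohort_scenario"))
  seeds <- .sub_seeds(scenario$seed, 3L)
  pc <- scenario$precancer[scenario$precancer > 0]
  n_part <- sum(pc)

  diagnosis_pool <- c("Ductal Carcinoma in situ",
                      "Familial Adenomatous Polyposis")
  tissue_pool <- c("Premalignant", "Atypia - hyperplasia",
                   "Premalignant - in situ")
  morph_pool <- c("M82110", "8213/0", "M82630", "8220/0")
  normal_diag <- c("Infiltrating duct carcinoma, NOS",
                   "Adenocarcinoma, NOS")
  normal_tissue <- c("Primary", "Metastatic", "Not Otherwise Specified")
  normal_morph <- c("8500/3", "8140/3", "")

  set.seed(seeds[1L])
  combo <- rep(names(pc), pc)
  has <- function(l) combo != "none" & grepl(l, combo, fixed = TRUE)
  A <- has("A"); B <- has("B"); C <- has("C"); D <- has("D")

  center <- ifelse(A,
                   scenario$precancer_centers[
                     1L + (seq_len(n_part) %% length(scenario$precancer_centers))],
                   scenario$other_centers[
                     1L + (seq_len(n_part) %% length(scenario$other_centers))])
  pid <- paste0(center, "_", seq_len(n_part))
  age <- ifelse(A, 0L, sample(35:85, n_part, replace = TRUE))
  diag <- ifelse(A, "Not Reported",
                 ifelse(B, diagnosis_pool[1L + seq_len(n_part) %% 2L],
                        sample(normal_diag, n_part, replace = TRUE)))
  # an A&B participant needs a precancer diagnosis, which is incompatible
  # with the Not-Reported requirement of the age-sentinel criterion; the
  # returned config therefore relaxes that requirement iff A&B is planted
  diag[A & B] <- diagnosis_pool[1L]
  relax_nr <- any(A & B)
  organ <- sample(c("Breast, NOS", "Upper lobe, lung", "Colon, NOS"),
                  n_part, replace = TRUE)
  clinical <- data.frame(
    participant_id = pid, center = center, age_at_diagnosis = age,
    primary_diagnosis = diag, tissue_or_organ_of_origin = organ)
  A_truth <- A

  set.seed(seeds[2L])
  bio_id <- c(paste0(pid, "_1"), paste0(pid, "_2"))
  bio_part <- c(pid, pid)
  first <- c(rep(TRUE, n_part), rep(FALSE, n_part))
  tt <- ifelse(first & rep(C, 2L),
               tissue_pool[1L + seq_along(bio_id) %% length(tissue_pool)],
               sample(normal_tissue, 2L * n_part, replace = TRUE))
  mc <- ifelse(first & rep(D, 2L),
               morph_pool[1L + seq_along(bio_id) %% length(morph_pool)],
               sample(normal_morph, 2L * n_part, replace = TRUE))
  biospecimens <- data.frame(
    biospecimen_id = bio_id, participant_id = bio_part,
    tumor_tissue_type = tt, histologic_morphology_code = mc)
  ord <- order(biospecimens$biospecimen_id)
  biospecimens <- biospecimens[ord, , drop = FALSE]
  rownames(biospecimens) <- NULL

  # modality plan over biospecimens, in biospecimen-id order
  set.seed(seeds[3L])
  plan <- rep(names(scenario$modalities), scenario$modalities)
  plan <- head(plan, nrow(biospecimens))
  plan <- c(plan, rep("neither", nrow(biospecimens) - length(plan)))
  files <- list()
  k <- 0L
  for (i in seq_len(nrow(biospecimens))) {
    mods <- switch(plan[i],
                   both = , both_null_release = c(scenario$modality_a,
                                                  scenario$modality_b),
                   a_only = scenario$modality_a,
                   b_only = scenario$modality_b,
                   neither = character(0))
    for (m in mods) {
      k <- k + 1L
      files[[k]] <- data.frame(
        htan_id = paste0(biospecimens$biospecimen_id[i], "_f", k),
        parent_biospecimen_id = biospecimens$biospecimen_id[i],
        center = sub("^(HTA[0-9]+)_.*$", "\\1",
                     biospecimens$biospecimen_id[i]),
        assay_type = m, level = "2", file_format = "ome.tiff",
        repository_file_id = sprintf("syn%07d", k),
        drs_uri = sprintf("drs://dg.4DFC:%08x",
                          sample.int(.Machine$integer.max, 1L)),
        data_release = if (plan[i] == "both_null_release") NA_character_
                       else "Release 5.0")
    }
  }
  file_metadata <- if (k) do.call(rbind, files) else
    data.frame(htan_id = character(0), parent_biospecimen_id = character(0),
               center = character(0), assay_type = character(0),
               level = character(0), file_format = character(0),
               repository_file_id = character(0), drs_uri = character(0),
               data_release = character(0))

  nodes <- rbind(
    data.frame(htan_id = pid, node_kind = "participant", parent_ids = "",
               center = center, assay_type = NA_character_,
               level = NA_character_, drs_uri = NA_character_,
               data_release = NA_character_),
    data.frame(htan_id = biospecimens$biospecimen_id,
               node_kind = "biospecimen",
               parent_ids = biospecimens$participant_id,
               center = sub("^(HTA[0-9]+)_.*$", "\\1",
                            biospecimens$biospecimen_id),
               assay_type = NA_character_, level = NA_character_,
               drs_uri = NA_character_, data_release = NA_character_),
    if (k) data.frame(htan_id = file_metadata$htan_id, node_kind = "file",
                      parent_ids = file_metadata$parent_biospecimen_id,
                      center = file_metadata$center,
                      assay_type = file_metadata$assay_type,
                      level = file_metadata$level,
                      drs_uri = file_metadata$drs_uri,
                      data_release = file_metadata$data_release)
  )
  rownames(nodes) <- NULL

  truth_pre <- data.frame(participant_id = pid, by_age_sentinel = A_truth,
                          by_diagnosis = B, by_tissue_type = C,
                          by_morphology = D)
  truth_pre <- truth_pre[A_truth | B | C | D, , drop = FALSE]
  truth_pre <- truth_pre[order(truth_pre$participant_id), , drop = FALSE]
  rownames(truth_pre) <- NULL
  cross_modal <- sort(biospecimens$biospecimen_id[plan == "both"])

  list(clinical = clinical, biospecimens = biospecimens,
       file_metadata = file_metadata, nodes = nodes,
       truth = list(precancer = truth_pre, cross_modal = cross_modal),
       config = precancer_config(scenario$precancer_centers,
                                 require_not_reported = !relax_nr))
}

#' Generate a synthetic tidy count table
#'
#' Negative-binomial counts at a requested sparsity: each (cell, feature)
#' pair is observed with probability `1 - sparsity` and observed entries
#' draw a strictly positive count (NB + 1). Deterministic under the seed.
#'
#' @param n_cells,n_features Table dimensions.
#' @param sparsity Fraction of unobserved pairs, in `[0, 1)`.
#' @param seed Seed.
#' @param nb_size,nb_mu Negative-binomial shape and mean of the count
#'   magnitude (defaults size 2, mean 5 — overdispersed, as for UMI
#'   counts).
#' @return A tidy table (`cell_barcode`, `feature`, `value`).
#' @export
gen_tidy_counts <- function(n_cells, n_features, sparsity, seed = 1L,
                            nb_size = 2, nb_mu = 5) {
  if (sparsity < 0 || sparsity >= 1) {
    stop("`sparsity` must lie in [0, 1)", call. = FALSE)
  }
  set.seed(seed)
  cellnm <- sprintf("cell_%04d", seq_len(n_cells))
  featnm <- sprintf("gene_%04d", seq_len(n_features))
  keep <- runif(n_cells * n_features) >= sparsity
  idx <- which(keep)
  out <- data.frame(
    cell_barcode = cellnm[((idx - 1L) %% n_cells) + 1L],
    feature = featnm[((idx - 1L) %/% n_cells) + 1L],
    value = rnbinom(length(idx), size = nb_size, mu = nb_mu) + 1
  )
  out <- out[order(out$cell_barcode, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  out
}
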