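#' Run the full tunnel analysis pipeline over a structure series
#'
#' Orchestrates every analysis stage over a labeled series of
#' structures (typically a pH series): per-structure B-factor summary
#' and region report, cross-structure highest-fluctuation
#' classification, enzyme-substrate interaction tables with subsites,
#' sugar ring-face calls, chi1 rotamer transitions, and cell metrics
#' where a unit cell is present. Reports are written as TSV (plus a
#' JSON summary) under `out_dir`; two runs with identical inputs
#' produce byte-identical files. Structure labels double as the series
#' axis (e.g. `"pH5"`); pH is never inferred from the files, which do
#' not encode it.
#'
#' @param inputs Named list: each element a `structure3d` or a path to
#'   a PDB file. Names are the labels; they must be unique.
#' @param out_dir Output directory (created if needed). `NULL` skips
#'   writing and just returns the bundle.
#' @param region_map A `region_map`, or a YAML path/string of
#'   overrides for [load_region_map()].
#' @param hbond_cutoff,saltbridge_cutoff Interaction cutoffs in
#'   angstroms (must be positive).
#' @param face_reference `"roof"` (centroid of the lid-loop residues)
#'   or a numeric 3-vector.
#' @param chain Chain to analyze (default: chain A when present).
#' @return Invisibly, a list with components `bfactor`,
#'   `classification`, `interactions`, `faces`, `rotamers`, `cell` and
#'   `files` (paths written).
#' @examples
#' s1 <- make_bfactor_fixture(10, b_profile = 10)
#' s2 <- make_bfactor_fixture(10, b_profile = seq(10, 40, length.out = 10))
#' out <- run_pipeline(list(pH5 = s1, pH7 = s2),
#'                     residues = 1:10, out_dir = NULL)
#' out$classification$counts
#' @param residues Residue set for the classification and rotamer
#'   stages (default: the region map's 24 substrate-interacting
#'   residues).
#' @param catalytic_point Optional explicit reference point for
#'   subsite assignment, forwarded to [assign_subsites()].
#' @export
run_pipeline <- function(inputs, out_dir = NULL,
                         region_map = default_region_map(),
                         hbond_cutoff = 3.6, saltbridge_cutoff = 4.0,
                         face_reference = "roof", chain = NULL,
                         residues = NULL, catalytic_point = NULL) {
  stopifnot(is.list(inputs), length(inputs) >= 1L)
  labels <- names(inputs)
  if (is.null(labels) || anyDuplicated(labels) || any(!nzchar(labels))) {
    stop("inputs must be uniquely named (labels)")
  }
  if (hbond_cutoff <= 0 || saltbridge_cutoff <= 0) {
    stop("cutoffs must be positive")
  }
  if (!inherits(region_map, "region_map")) {
    region_map <- load_region_map(region_map)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  structs <- stage("load", lapply(inputs, function(x) {
    if (inherits(x, "structure3d")) x else read_structure(x)
  }))
  if (is.null(residues)) residues <- region_map$interacting24

  bfac <- stage("bfactor", {
    summ <- do.call(rbind, lapply(labels, function(lb) {
      s <- structs[[lb]]
      data.frame(
        label = lb,
        overall_mean_b = mean_bfactor(s),
        backbone_mean_b = mean_bfactor(s, backbone = TRUE,
                                       hetero = FALSE),
        protein_mean_b = bfactor_profile(s, chain = chain)$protein_mean,
        stringsAsFactors = FALSE
      )
    }))
    regions <- do.call(rbind, lapply(labels, function(lb) {
      rep <- region_bfactor_report(structs[[lb]], region_map,
                                   chain = chain)
      if (nrow(rep$site_means) == 0L) return(NULL)
      cbind(label = lb, rep$site_means)
    }))
    list(summary = summ, site_means = regions)
  })

  classification <- if (length(structs) >= 2L) {
    stage("classification",
          highest_fluctuation_classification(structs, residues,
                                             chain = chain))
  } else NULL

  interactions <- stage("interactions", lapply(labels, function(lb) {
    tb <- tryCatch(
      interaction_table(structs[[lb]], region_map,
                        hbond_cutoff = hbond_cutoff,
                        saltbridge_cutoff = saltbridge_cutoff,
                        catalytic_point = catalytic_point),
      error = function(e) list(records = .empty_records(),
                               counts = c(h_bond = 0L,
                                          salt_bridge = 0L)))
    tb
  }))
  names(interactions) <- labels

  faces <- stage("faces", lapply(labels, function(lb) {
    s <- structs[[lb]]
    lig <- ligand_atoms(s)
    if (nrow(lig) == 0L) return(NULL)
    ref <- if (is.numeric(face_reference)) face_reference else
      tryCatch(roof_reference(s, chain = chain),
               error = function(e) NULL)
    key <- unique(lig[, c("chain", "resno", "resid")])
    do.call(rbind, lapply(seq_len(nrow(key)), function(i) {
      face <- if (is.null(ref)) NA_character_ else tryCatch(
        classify_face(s, ref, resno = key$resno[[i]],
                      chain = key$chain[[i]]),
        error = function(e) NA_character_)
      data.frame(label = lb, resno = key$resno[[i]],
                 resid = key$resid[[i]], face = face,
                 stringsAsFactors = FALSE)
    }))
  }))

  rotamers <- if (length(structs) >= 2L) {
    stage("rotamers", rotamer_transitions(structs, residues,
                                          chain = chain))
  } else NULL

  cell <- stage("cell", do.call(rbind, lapply(labels, function(lb) {
    s <- structs[[lb]]
    if (is.null(s$cell) || is.na(s$space_group)) return(NULL)
    cm <- tryCatch(cell_metrics(s), error = function(e) NULL)
    if (is.null(cm)) return(NULL)
    data.frame(label = lb, volume = cm$volume, vm = cm$vm,
               solvent = cm$solvent, stringsAsFactors = FALSE)
  })))

  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wtsv <- function(df, name) {
      if (is.null(df) || nrow(df) == 0L) return(invisible(NULL))
      path <- file.path(out_dir, name)
      utils::write.table(df, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      files <<- c(files, path)
    }
    wtsv(bfac$summary, "bfactor_summary.tsv")
    wtsv(bfac$site_means, "bfactor_sites.tsv")
    if (!is.null(classification)) {
      wtsv(classification$assignments, "classification.tsv")
      path <- file.path(out_dir, "classification_counts.json")
      jsonlite::write_json(as.list(classification$counts), path,
                           auto_unbox = TRUE)
      files <- c(files, path)
    }
    irec <- do.call(rbind, lapply(labels, function(lb) {
      r <- interactions[[lb]]$records
      if (nrow(r) == 0L) return(NULL)
      cbind(label = lb,
            r[, c("donor_resid", "donor_resno", "donor_atom", "site",
                  "surface", "acceptor_resid", "acceptor_resno",
                  "acceptor_atom", "subsite", "kind", "distance")])
    }))
    if (!is.null(irec)) irec$distance <- round(irec$distance, 1)
    wtsv(irec, "interactions.tsv")
    wtsv(do.call(rbind, faces), "ring_faces.tsv")
    if (!is.null(rotamers)) wtsv(rotamers, "rotamers.tsv")
    wtsv(cell, "cell_metrics.tsv")
  }

  invisible(list(bfactor = bfac, classification = classification,
                 interactions = interactions, faces = faces,
                 rotamers = rotamers, cell = cell, files = files))
}
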