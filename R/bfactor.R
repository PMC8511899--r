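#' Mean B-factor over an atom selection
#'
#' Unweighted arithmetic mean of the isotropic B-factors of the selected
#' atoms. With no selection clauses this is the whole-molecule average
#' (protein plus ligands, ions and waters), the headline number quoted
#' per structure; pass `backbone = TRUE` (optionally with
#' `hetero = FALSE`) for the backbone average.
#'
#' @inheritParams select_atoms
#' @param ... Selection clauses forwarded to [select_atoms()].
#' @return Mean B in square angstroms.
#' @examples
#' s <- make_bfactor_fixture(n_residues = 5, b_profile = 10)
#' mean_bfactor(s)
#' @export
mean_bfactor <- function(struct, ...) {
  sel <- select_atoms(struct, ...)
  if (nrow(sel) == 0L) stop("empty selection")
  mean(sel$b)
}

#' Per-residue B-factor profile with per-structure scaling
#'
#' Computes, for every protein residue, the all-atom, backbone and
#' side-chain mean B, and a dimensionless scaled value: the residue
#' all-atom mean divided by the protein-only mean B of the structure.
#' Scaling removes resolution and crystal-packing bias so profiles from
#' structures refined at different resolutions can be compared; the
#' protein-only denominator avoids bias from differing water counts.
#' By construction the atom-count-weighted mean of the scaled values
#' over protein residues is exactly 1.
#'
#' @param struct A `structure3d` object.
#' @param chain Restrict to one chain (default: all protein chains).
#' @return A `bfactor_profile`: list with `residues` (data frame:
#'   `chain`, `resno`, `resid`, `n_atoms`, `b_all`, `b_backbone`,
#'   `b_side`, `scaled`), `overall_mean` (all atoms in the model) and
#'   `protein_mean`.
#' @examples
#' s <- make_bfactor_fixture(n_residues = 2, b_profile = c(10, 30))
#' bfactor_profile(s)$residues$scaled
#' @export
bfactor_profile <- function(struct, chain = NULL) {
  stopifnot(inherits(struct, "structure3d"))
  at <- struct$atoms
  prot <- at[.is_protein(at), , drop = FALSE]
  if (!is.null(chain)) prot <- prot[prot$chain %in% chain, , drop = FALSE]
  if (nrow(prot) == 0L) stop("no protein atoms in structure")
  protein_mean <- mean(prot$b)
  if (protein_mean == 0) stop("protein mean B-factor is zero; cannot scale")

  key <- paste(prot$chain, prot$resno, sep = "\r")
  idx <- split(seq_len(nrow(prot)), factor(key, levels = unique(key)))
  rows <- lapply(idx, function(i) {
    r <- prot[i, , drop = FALSE]
    bb <- r$elety %in% .BACKBONE
    data.frame(
      chain = r$chain[[1L]], resno = r$resno[[1L]], resid = r$resid[[1L]],
      n_atoms = nrow(r),
      b_all = mean(r$b),
      b_backbone = if (any(bb)) mean(r$b[bb]) else NA_real_,
      b_side = if (any(!bb)) mean(r$b[!bb]) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res$scaled <- res$b_all / protein_mean

  structure(
    list(residues = res,
         overall_mean = mean(at$b),
         protein_mean = protein_mean),
    class = "bfactor_profile"
  )
}

#' @export
print.bfactor_profile <- function(x, ...) {
  cat("bfactor_profile: ", nrow(x$residues), " residues; overall mean ",
      sprintf("%.2f", x$overall_mean), " A^2, protein mean ",
      sprintf("%.2f", x$protein_mean), " A^2\n", sep = "")
  invisible(x)
}

#' Site-wise B-factor report over a region map
#'
#' For each site (entry/tunnel/exit) of a region map, the mean B over
#' all atoms of the member residues present in the structure, plus
#' per-residue raw and scaled values. Residues absent from the model
#' (unresolved density) are listed and excluded; a site with no resolved
#' member residues is reported as `NA`.
#'
#' @param struct A `structure3d` object.
#' @param region_map A `region_map` (default [default_region_map()]).
#' @param chain Chain to analyze (default `"A"` when present, else the
#'   first protein chain).
#' @return List with `site_means` (data frame `site`, `n_residues`,
#'   `mean_b`), `residues` (per-residue table with `site`, `raw_b`,
#'   `scaled_b`) and `missing` (residue ids absent from the model).
#' @export
region_bfactor_report <- function(struct, region_map = default_region_map(),
                                  chain = NULL) {
  stopifnot(inherits(struct, "structure3d"),
            inherits(region_map, "region_map"))
  at <- struct$atoms
  prot <- at[.is_protein(at), , drop = FALSE]
  if (is.null(chain)) {
    chains <- unique(prot$chain)
    chain <- if ("A" %in% chains) "A" else chains[[1L]]
  }
  prot <- prot[prot$chain %in% chain, , drop = FALSE]
  prof <- bfactor_profile(struct, chain = chain)

  res_rows <- list()
  missing <- character(0)
  site_means <- data.frame(site = character(0), n_residues = integer(0),
                           mean_b = numeric(0), stringsAsFactors = FALSE)
  for (site in c("entry", "tunnel", "exit")) {
    ids <- region_map$sites[[site]]
    nums <- region_resno(ids)
    present <- nums %in% prot$resno
    missing <- c(missing, ids[!present])
    sel <- prot[prot$resno %in% nums[present], , drop = FALSE]
    site_means <- rbind(site_means, data.frame(
      site = site, n_residues = sum(present),
      mean_b = if (nrow(sel)) mean(sel$b) else NA_real_,
      stringsAsFactors = FALSE
    ))
    for (k in which(present)) {
      pr <- prof$residues[prof$residues$resno == nums[[k]], , drop = FALSE]
      res_rows[[length(res_rows) + 1L]] <- data.frame(
        site = site, residue = ids[[k]], resno = nums[[k]],
        raw_b = pr$b_all[[1L]], scaled_b = pr$scaled[[1L]],
        stringsAsFactors = FALSE
      )
    }
  }
  residues <- if (length(res_rows)) do.call(rbind, res_rows) else
    data.frame(site = character(0), residue = character(0),
               resno = integer(0), raw_b = numeric(0),
               scaled_b = numeric(0))
  list(site_means = site_means, residues = residues, missing = missing)
}

#' Cross-structure highest-fluctuation classification
#'
#' Given a labeled series of structures (e.g. a pH series) and a residue
#' set, finds for every residue the structure in which its scaled (or
#' raw) per-residue B is highest, and tallies wins per structure. Because
#' scaling is per structure, the classification is invariant to a global
#' rescaling of any single structure's B column. A residue unresolved in
#' some structures competes only among the structures that resolve it;
#' residues resolved nowhere are skipped with a warning. Ties are broken
#' by the order the structures are supplied.
#'
#' @param structs Named list of `structure3d` objects; names are the
#'   series labels (e.g. `"pH5"`).
#' @param residues Residue ids (`"Y38"` style) or integer residue
#'   numbers.
#' @param scaled Use scaled per-residue B (default) or raw means.
#' @param chain Chain to analyze in each structure (default as in
#'   [region_bfactor_report()]).
#' @return List with `assignments` (data frame `residue`, `resno`,
#'   `label`, `value`), `counts` (named integer vector over labels,
#'   summing to the number of classified residues) and `skipped`.
#' @export
highest_fluctuation_classification <- function(structs, residues,
                                               scaled = TRUE,
                                               chain = NULL) {
  stopifnot(is.list(structs), length(structs) >= 1L,
            !is.null(names(structs)), all(nzchar(names(structs))))
  labels <- names(structs)
  ids <- if (is.character(residues)) residues else as.character(residues)
  nums <- if (is.character(residues)) region_resno(residues) else
    as.integer(residues)

  profs <- lapply(structs, function(s) {
    ch <- chain
    if (is.null(ch)) {
      prot <- s$atoms[.is_protein(s$atoms), , drop = FALSE]
      chains <- unique(prot$chain)
      ch <- if ("A" %in% chains) "A" else chains[[1L]]
    }
    bfactor_profile(s, chain = ch)$residues
  })

  rows <- list()
  skipped <- character(0)
  for (k in seq_along(nums)) {
    vals <- vapply(profs, function(p) {
      hit <- p$resno == nums[[k]]
      if (!any(hit)) return(NA_real_)
      if (scaled) p$scaled[hit][[1L]] else p$b_all[hit][[1L]]
    }, numeric(1))
    if (all(is.na(vals))) {
      skipped <- c(skipped, ids[[k]])
      next
    }
    win <- which.max(vals)  # NAs never win; first max wins on ties
    rows[[length(rows) + 1L]] <- data.frame(
      residue = ids[[k]], resno = nums[[k]], label = labels[[win]],
      value = vals[[win]], stringsAsFactors = FALSE
    )
  }
  if (length(skipped)) {
    warning("residue(s) unresolved in every structure: ",
            paste(skipped, collapse = ", "))
  }
  assignments <- if (length(rows)) do.call(rbind, rows) else
    data.frame(residue = character(0), resno = integer(0),
               label = character(0), value = numeric(0))
  counts <- table(factor(assignments$label, levels = labels))
  list(assignments = assignments,
       counts = setNames(as.integer(counts), labels),
       skipped = skipped)
}
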