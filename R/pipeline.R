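#' Generate and write a synthetic comparison bundle
#'
#' Thin orchestration over [sim_config()] and [make_comparison_bundle()]:
#' builds the bundle for a seed and writes every input file into `dir`.
#' Rerunning with the same configuration reproduces the directory.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param ... Passed to [sim_config()].
#' @return The bundle list, invisibly (with `$paths`).
#' @export
simulate_bundle <- function(dir, seed = 1L, ...) {
  config <- sim_config(seed = seed, ...)
  invisible(make_comparison_bundle(config, dir = dir))
}

#' Read a comparison bundle from a directory
#'
#' Reads the file layout written by [simulate_bundle()] back into memory
#' through the package's format readers. Missing structure/PAE/track files
#' are tolerated (the comparison degrades gracefully to its sequence-side
#' results).
#'
#' @param dir Bundle directory.
#' @return A bundle-shaped list (`frame`, `models`, `complexes`, `pae`,
#'   `adopt`, `regions`, `truth` when present).
#' @export
read_bundle <- function(dir) {
  frame <- read_alignment(file.path(dir, "family_aln.fasta"))
  species <- setdiff(frame$id, "root")
  grab <- function(paths, reader, ...) {
    ok <- file.exists(paths)
    if (!any(ok)) return(NULL)
    setNames(lapply(paths[ok], reader, ...), names(paths)[ok])
  }
  models <- grab(setNames(file.path(dir, paste0(species, ".pdb")), species),
                 read_structure)
  complexes <- grab(
    setNames(file.path(dir, paste0(species, "_complex.pdb")), species),
    read_structure
  )
  pae <- grab(setNames(file.path(dir, paste0(species, "_pae.json")), species),
              read_pae)
  adopt <- grab(
    setNames(file.path(dir, paste0(species, "_adopt.tsv")), species),
    read_score_track, kind = "adopt_z"
  )
  regions <- NULL
  if (file.exists(file.path(dir, "regions.tsv"))) {
    regions <- read_regions(file.path(dir, "regions.tsv"),
                            reference_id = "root")
  }
  truth <- NULL
  if (file.exists(file.path(dir, "truth.json"))) {
    truth <- jsonlite::fromJSON(file.path(dir, "truth.json"))
  }
  list(frame = frame, models = models, complexes = complexes, pae = pae,
       adopt = adopt, regions = regions, truth = truth)
}

#' Run the full cross-species comparison
#'
#' Orchestrates every stage of the pipeline on a bundle (in-memory or a
#' directory): pairwise sequence divergence, per-species order masks,
#' lineage-specific substitutions against the ancestor with stratified exact
#' tests, all pairwise superpositions with confidence-gated classification
#' and species-specific difference calling, and hydrogen-bond / contact
#' catalogs with their category comparisons. Structure stages are skipped
#' (with a note in `$skipped`) when the bundle has no models.
#'
#' @param bundle A bundle list from [make_comparison_bundle()] /
#'   [read_bundle()], or a bundle directory path.
#' @param ancestor_id Alignment row used as the ancestral node, default
#'   `"root"`.
#' @param rmsd_threshold Matched/different deviation threshold (Angstrom).
#' @param prune_cutoff Superposition prune cutoff (Angstrom).
#' @param pae_cutoff Contact PAE cutoff (Angstrom).
#' @param dist_cutoff Contact distance cutoff (Angstrom).
#' @param hbond_dist_tol,hbond_angle_tol,min_separation Hydrogen-bond
#'   tolerances and intra-chain separation rule.
#' @param plddt_threshold Confidence threshold on plDDT.
#' @param adopt_threshold Order threshold on the disorder Z-score.
#' @param miyata_cap Miyata class cap.
#' @param out_dir Optional directory for TSV/JSON reports.
#' @return An object of class `ortho_comparison`; see [glance.ortho_comparison()].
#' @export
run_comparison <- function(bundle, ancestor_id = "root",
                           rmsd_threshold = 2, prune_cutoff = 2,
                           pae_cutoff = 5, dist_cutoff = 4,
                           hbond_dist_tol = 0.4, hbond_angle_tol = 20,
                           min_separation = 5, plddt_threshold = 70,
                           adopt_threshold = 3, miyata_cap = 4,
                           out_dir = NULL) {
  if (is.character(bundle)) bundle <- read_bundle(bundle)
  frame <- bundle$frame
  species <- setdiff(frame$id, ancestor_id)
  skipped <- character()
  thresholds <- list(
    rmsd_threshold = rmsd_threshold, prune_cutoff = prune_cutoff,
    pae_cutoff = pae_cutoff, dist_cutoff = dist_cutoff,
    hbond_dist_tol = hbond_dist_tol, hbond_angle_tol = hbond_angle_tol,
    min_separation = min_separation, plddt_threshold = plddt_threshold,
    adopt_threshold = adopt_threshold, miyata_cap = miyata_cap
  )

  divergence <- divergence_table(frame)

  # per-species order masks from whatever tracks exist
  masks <- setNames(lapply(species, function(sp) {
    conf <- NULL; ord <- NULL
    if (!is.null(bundle$models[[sp]])) {
      conf <- classify_confidence(plddt_track(bundle$models[[sp]], id = sp),
                                  threshold = plddt_threshold)
    }
    if (!is.null(bundle$adopt[[sp]])) {
      ord <- classify_order(bundle$adopt[[sp]], threshold = adopt_threshold)
    }
    if (is.null(conf) && is.null(ord)) return(NULL)
    consensus_mask(conf, ord)
  }), species)
  if (all(vapply(masks, is.null, logical(1)))) {
    skipped <- c(skipped, "order masks (no plDDT or disorder tracks)")
    masks <- NULL
  }

  substitutions <- purrr::map_dfr(
    species, function(sp)
      infer_lineage_substitutions(frame, ancestor_id, sp, miyata_cap)
  )
  indels <- purrr::map_dfr(
    species, function(sp) infer_lineage_indels(frame, ancestor_id, sp)
  )
  sub_counts <- stratify_substitutions(substitutions, frame,
                                       regions = bundle$regions,
                                       masks = masks)
  sub_tests <- compare_substitution_categories(sub_counts)

  superpositions <- NULL; specific <- NULL
  if (!is.null(bundle$models) && length(bundle$models) >= 2L) {
    ids <- names(bundle$models)
    pairs <- utils::combn(ids, 2, simplify = FALSE)
    superpositions <- setNames(lapply(pairs, function(pr) {
      pairing <- pair_residues(frame, pr[1], pr[2],
                               bundle$models[[pr[1]]],
                               bundle$models[[pr[2]]])
      res <- matchmaker_superpose(pairing, prune_cutoff = prune_cutoff,
                                  species_a = pr[1], species_b = pr[2])
      classify_pairs(res, masks[[pr[1]]], masks[[pr[2]]],
                     rmsd_threshold = rmsd_threshold,
                     plddt_threshold = plddt_threshold)
    }), vapply(pairs, paste, "", collapse = "|"))
    specific <- purrr::map_dfr(ids, function(focal) {
      hits <- species_specific_differences(superpositions, focal)
      if (nrow(hits) > 0) hits$focal <- focal
      hits
    })
  } else {
    skipped <- c(skipped, "superposition (no structure models)")
  }

  hbonds <- NULL; hbond_cmp <- NULL; contacts <- NULL; contact_cmp <- NULL
  if (!is.null(bundle$complexes) && length(bundle$complexes) >= 1L) {
    hbonds <- lapply(bundle$complexes, detect_hbonds,
                     dist_tol = hbond_dist_tol, angle_tol = hbond_angle_tol,
                     min_separation = min_separation)
    contacts <- purrr::imap(bundle$complexes, function(cx, sp) {
      parts <- structure_chains(cx)
      if (length(parts) < 2L) return(empty_contacts())
      interface_contacts(parts[[1]], parts[[2]], pae = bundle$pae[[sp]],
                         pae_cutoff = pae_cutoff, dist_cutoff = dist_cutoff)
    })
    focal_chain <- unique(bundle$complexes[[1]]$chain)[1]
    hbond_cmp <- compare_catalogs(hbonds, frame, regions = bundle$regions,
                                  masks = masks, chain = focal_chain)
    contact_cmp <- compare_catalogs(contacts, frame,
                                    regions = bundle$regions,
                                    masks = masks, chain = focal_chain)
  } else {
    skipped <- c(skipped, "interactions (no complex models)")
  }

  out <- structure(
    list(
      thresholds = thresholds, ancestor_id = ancestor_id,
      species = species, divergence = divergence, masks = masks,
      substitutions = substitutions, indels = indels,
      substitution_counts = sub_counts, substitution_tests = sub_tests,
      od_ratio = ordered_disordered_ratio(sub_counts),
      superpositions = superpositions, species_specific = specific,
      hbonds = hbonds, hbond_comparison = hbond_cmp,
      contacts = contacts, contact_comparison = contact_cmp,
      skipped = skipped
    ),
    class = "ortho_comparison"
  )
  if (!is.null(out_dir)) write_comparison(out, out_dir)
  out
}

#' @export
print.ortho_comparison <- function(x, ...) {
  cat("<ortho_comparison>\n")
  cat(sprintf("  species: %s (ancestor: %s)\n",
              paste(x$species, collapse = ", "), x$ancestor_id))
  cat(sprintf("  substitutions: %d; indel columns: %d\n",
              nrow(x$substitutions), nrow(x$indels)))
  if (!is.null(x$superpositions)) {
    cat(sprintf("  superposed pairs: %d; species-specific different columns: %d\n",
                length(x$superpositions),
                if (is.null(x$species_specific)) 0L
                else nrow(x$species_specific)))
  }
  if (!is.null(x$hbond_comparison)) {
    sig <- sum(x$hbond_comparison$tests$p_adjusted < 0.05, na.rm = TRUE) +
      sum(x$contact_comparison$tests$p_adjusted < 0.05, na.rm = TRUE)
    cat(sprintf("  significant interaction category differences: %d\n", sig))
  }
  for (s in x$skipped) cat(sprintf("  [skipped] %s\n", s))
  invisible(x)
}

# write all tables with a '#'-prefixed metadata header
write_comparison <- function(x, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- c(
    sprintf("# orthostruct %s",
            as.character(utils::packageVersion("orthostruct"))),
    sprintf("# ancestor: %s", x$ancestor_id),
    sprintf("# %s", paste(names(x$thresholds), unlist(x$thresholds),
                          sep = "=", collapse = " "))
  )
  emit <- function(tbl, name) {
    path <- file.path(out_dir, name)
    writeLines(hdr, path)
    readr::write_tsv(tbl, path, append = TRUE, col_names = TRUE)
  }
  emit(x$divergence, "divergence.tsv")
  emit(x$substitutions, "substitutions.tsv")
  emit(x$substitution_counts, "substitution_counts.tsv")
  emit(x$substitution_tests, "substitution_tests.tsv")
  if (!is.null(x$species_specific)) {
    emit(x$species_specific, "species_specific_differences.tsv")
  }
  if (!is.null(x$superpositions)) {
    emit(purrr::map_dfr(x$superpositions, tidy), "superposition_pairs.tsv")
  }
  if (!is.null(x$hbond_comparison)) {
    emit(purrr::imap_dfr(x$hbonds,
                         ~ dplyr::mutate(.x, species = .y)), "hbonds.tsv")
    emit(x$hbond_comparison$tests, "hbond_tests.tsv")
    emit(purrr::imap_dfr(x$contacts,
                         ~ dplyr::mutate(.x, species = .y)), "contacts.tsv")
    emit(x$contact_comparison$tests, "contact_tests.tsv")
  }
  invisible(out_dir)
}
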