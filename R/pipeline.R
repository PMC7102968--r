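# Orchestration: run the full complex characterization (interface,
# nucleic geometry, pseudo-symmetry) from one configuration, compare a
# reference complex against a list of targets with the domain-anchored
# protocol, and derive thermodynamic tables.  Reports are written as
# JSON + TSV with every threshold logged for provenance.

#' Analysis configuration
#'
#' @param structure Path to a structure file, or a `structure_model`.
#' @param protein_chains Length-2 vector: the dimer protomer chains.
#' @param nucleic_chains Nucleic-acid chain(s).
#' @param thresholds See [interface_thresholds()].
#' @param temperature_K Temperature for thermodynamic derivations.
#' @param output_dir Directory for report files (`NULL` = do not
#'   write).
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(structure, protein_chains, nucleic_chains,
                            thresholds = interface_thresholds(),
                            temperature_K = 298, output_dir = NULL) {
  structure(list(structure = structure, protein_chains = protein_chains,
                 nucleic_chains = nucleic_chains, thresholds = thresholds,
                 temperature_K = temperature_K, output_dir = output_dir),
            class = "analysis_config")
}

.load_model <- function(structure) {
  if (inherits(structure, "structure_model")) return(structure)
  read_structure(structure)
}

.check_chains <- function(model, chains, role) {
  missing <- setdiff(chains, unique(model$atoms$chain))
  if (length(missing) > 0)
    stop("configuration error (", role, "): chain(s) ",
         paste(missing, collapse = ", "), " not present in '",
         model$identifier, "'")
}

#' Analyze a dimer-nucleic-acid complex
#'
#' Runs the interface census (contacts, buried areas, typed
#' interactions), nucleic-acid geometry annotation (torsions, base
#' pairs, stacking runs/flips) and the dyad pseudo-symmetry test in
#' sequence, and optionally writes a JSON report plus TSV tables.
#'
#' @param config An [analysis_config()].
#' @return A `complex_report` list with elements `interface`,
#'   `torsions`, `base_pairs`, `stacking`, `symmetry`, `config`.
#' @export
analyze_complex <- function(config) {
  model <- .load_model(config$structure)
  .check_chains(model, config$protein_chains, "protein dimer")
  .check_chains(model, config$nucleic_chains, "nucleic component")
  th <- config$thresholds
  prot <- select_atoms(model, chains = config$protein_chains,
                       kinds = "amino_acid")
  nuc <- select_atoms(model, chains = config$nucleic_chains,
                      kinds = "nucleotide")
  iface <- interface_summary(model, prot, nuc, thresholds = th)
  torsions <- lapply(config$nucleic_chains, function(ch)
    backbone_torsions(model, ch))
  names(torsions) <- config$nucleic_chains
  pairs <- detect_base_pairs(model, config$nucleic_chains,
                             hbond_dist = th$hbond_dist,
                             hbond_angle = th$hbond_angle)
  stacking <- lapply(config$nucleic_chains, function(ch)
    stacking_runs_and_flips(model, ch, th$stack_dist, th$stack_angle))
  names(stacking) <- config$nucleic_chains
  axis <- dimer_dyad_axis(model, config$protein_chains[1],
                          config$protein_chains[2])
  corr <- rna_self_correspondence(model, config$nucleic_chains, axis)
  report <- structure(list(identifier = model$identifier,
                           interface = iface, torsions = torsions,
                           base_pairs = pairs, stacking = stacking,
                           symmetry = list(axis = axis,
                                           correspondence = corr),
                           config = config),
                      class = "complex_report")
  if (!is.null(config$output_dir)) write_complex_report(report,
                                                        config$output_dir)
  report
}

#' Write a complex report as JSON + TSV
#'
#' @param report A `complex_report` from [analyze_complex()].
#' @param dir Output directory (created if needed).
#' @return The JSON path, invisibly.
#' @export
write_complex_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  iface <- report$interface
  ax <- report$symmetry$axis
  js <- list(
    identifier = report$identifier,
    schema_version = "1.0",
    package_version = as.character(utils::packageVersion("aptcomplex")),
    thresholds = iface$thresholds,
    contact_residues = iface$census$residues,
    n_contact_residues = iface$census$n_residues,
    buried_area = list(per_domain = as.list(iface$buried_area$per_domain),
                       total = iface$buried_area$total),
    hydrogen_bonds = iface$hydrogen_bonds,
    bidentate = attr(iface$hydrogen_bonds, "bidentate"),
    ring_interactions = iface$ring_interactions,
    base_pairs = report$base_pairs,
    stacking_runs = lapply(report$stacking, `[[`, "runs"),
    flipped = lapply(report$stacking, `[[`, "flipped"),
    dyad_axis = list(point = ax$point, direction = ax$direction,
                     angle = ax$angle, screw = ax$screw),
    correspondence_rmsd = report$symmetry$correspondence$rmsd)
  json_path <- file.path(dir, paste0(report$identifier, "_report.json"))
  jsonlite::write_json(js, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  utils::write.table(iface$census$contacts,
                     file.path(dir, paste0(report$identifier,
                                           "_contacts.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tor <- do.call(rbind, report$torsions)
  utils::write.table(tor,
                     file.path(dir, paste0(report$identifier,
                                           "_torsions.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$symmetry$correspondence$table,
                     file.path(dir, paste0(report$identifier,
                                           "_correspondence.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(json_path)
}

#' Compare a reference complex against target structures
#'
#' One row per target: anchor-domain r.m.s.d., probe-domain r.m.s.d.
#' under the anchor transform, and averaged inter-residue distances at
#' selected marker residues.
#'
#' @param reference A `structure_model` (or path) of the reference
#'   complex.
#' @param ref_chains Protomer chains of the reference dimer.
#' @param targets Named list; each element a list with `structure`
#'   and `chains`.
#' @param anchor,probe `domain_definition`s.
#' @param marker_residues Residue numbers for the averaged
#'   inter-residue distances (default 55, 12, 42).
#' @return Data frame shaped like a structure-comparison table.
#' @export
compare_complexes <- function(reference, ref_chains, targets,
                              anchor = ebd_domain(), probe = nbd_domain(),
                              marker_residues = c(55, 12, 42)) {
  ref <- .load_model(reference)
  rows <- lapply(names(targets), function(nm) {
    tgt <- targets[[nm]]
    mod <- .load_model(tgt$structure)
    res <- anchored_domain_rmsd(ref, mod, ref_chains, tgt$chains,
                                anchor, probe)
    pairing <- res$chain_pairing
    dists <- vapply(marker_residues, function(rn)
      inter_residue_distance(ref, mod, names(pairing), unname(pairing),
                             rn, transform = res$transform),
      numeric(1))
    cbind(data.frame(target = nm, anchor_rmsd = res$anchor_rmsd,
                     probe_rmsd = res$probe_rmsd,
                     n_anchor_pairs = res$n_anchor_pairs,
                     n_probe_pairs = res$n_probe_pairs,
                     stringsAsFactors = FALSE),
          stats::setNames(as.data.frame(t(dists)),
                          paste0("residue_", marker_residues)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Derive a thermodynamic table from binding parameters
#'
#' Input rows carry K_d (nanomolar unless `kd_unit` says otherwise),
#' stoichiometry n, dH (kJ/mol) and dS (J/mol/K); the output appends
#' TdS, -TdS, dG, dG from K_d, the consistency residual, and the
#' fold-change of K_d against a named reference row.
#'
#' @param params Data frame with columns `id`, `K_d`, `n`, `dH`,
#'   `dS`, or a path to such a TSV.
#' @param reference `id` of the reference row for fold-changes
#'   (`NULL` = none).
#' @param T_K Temperature (K), default 298.
#' @param kd_unit Unit of the `K_d` column: `"nM"` (default), `"uM"`
#'   or `"M"`.
#' @return The input data frame with derived columns appended.
#' @export
thermo_table <- function(params, reference = NULL, T_K = 298,
                         kd_unit = c("nM", "uM", "M")) {
  kd_unit <- match.arg(kd_unit)
  if (is.character(params) && length(params) == 1)
    params <- utils::read.table(params, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
  scale <- c(nM = 1e-9, uM = 1e-6, M = 1)[[kd_unit]]
  kd_molar <- params$K_d * scale
  der <- lapply(seq_len(nrow(params)), function(i) {
    if (is.na(kd_molar[i]))
      return(list(TdS = NA, minus_TdS = NA, dG = NA, dG_from_Kd = NA,
                  residual = NA))
    derive_thermo(binding_parameters(kd_molar[i], params$n[i],
                                     params$dH[i], params$dS[i], T_K))
  })
  params$TdS <- vapply(der, `[[`, numeric(1), "TdS")
  params$minus_TdS <- vapply(der, `[[`, numeric(1), "minus_TdS")
  params$dG <- vapply(der, `[[`, numeric(1), "dG")
  params$dG_from_Kd <- vapply(der, `[[`, numeric(1), "dG_from_Kd")
  params$residual <- vapply(der, `[[`, numeric(1), "residual")
  if (!is.null(reference)) {
    ref_i <- match(reference, params$id)
    if (is.na(ref_i)) stop("reference row '", reference, "' not found")
    params$fold_change <- vapply(seq_len(nrow(params)), function(i) {
      if (is.na(kd_molar[i])) return(NA_real_)
      fold_change(kd_molar[i], kd_molar[ref_i])$ratio
    }, numeric(1))
  }
  params
}
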