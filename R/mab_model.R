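# Antibody chain model, tryptic digestion, and PQA target-species panel.

#' Construct an antibody chain
#'
#' @param chain_id `"light"` or `"heavy"`.
#' @param residues One-letter amino-acid string (standard 20 letters).
#' @param name Free-text chain name.
#' @return A `chain_sequence` object. Positions are 1-based.
#' @export
chain_sequence <- function(chain_id, residues, name = chain_id) {
  chain_id <- match.arg(chain_id, c("light", "heavy"))
  residues <- toupper(gsub("[[:space:]]", "", residues))
  if (!nzchar(residues)) stop("chain has no residues")
  letters <- strsplit(residues, "")[[1]]
  bad <- which(!letters %in% names(AA_MONO))
  if (length(bad)) {
    stop("invalid residue '", letters[bad[1]], "' at position ", bad[1],
         " of chain '", name, "'")
  }
  structure(list(chain_id = chain_id, name = name, residues = residues),
            class = "chain_sequence")
}

#' @export
print.chain_sequence <- function(x, ...) {
  cat(sprintf("<%s chain '%s', %d aa>\n", x$chain_id, x$name,
              nchar(x$residues)))
  invisible(x)
}

#' Read antibody chains from a FASTA file
#'
#' Each record header must contain the token `light` or `heavy`
#' (case-insensitive) identifying the chain.
#'
#' @param path Path to a FASTA file.
#' @return List of [chain_sequence()] objects in file order.
#' @export
parse_chain_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0) stop("no FASTA records in ", path)
  lapply(seq_along(seqs), function(i) {
    header <- names(seqs)[i]
    toks <- tolower(strsplit(header, "[[:space:]|_:;,-]+")[[1]])
    id <- intersect(c("light", "heavy"), toks)
    if (length(id) != 1) {
      stop("FASTA header '", header,
           "' must contain exactly one of the tokens 'light'/'heavy'")
    }
    chain_sequence(id, as.character(seqs[[i]]), name = header)
  })
}

#' Tryptic in-silico digestion
#'
#' Cleaves C-terminal of K/R except when the next residue is proline
#' (Keil rule), producing all peptides with up to `max_missed` missed
#' cleavages.
#'
#' @param chain A [chain_sequence()].
#' @param max_missed Maximum number of missed cleavage sites (default 1).
#' @return data.frame with columns `chain_id`, `start`, `end` (1-based,
#'   inclusive), `sequence`, `missed_cleavages`.
#' @examples
#' digest(chain_sequence("heavy", "AKRGCK"), max_missed = 1)
#' @export
digest <- function(chain, max_missed = 1) {
  stopifnot(inherits(chain, "chain_sequence"), max_missed >= 0)
  s <- strsplit(chain$residues, "")[[1]]
  n <- length(s)
  # cleavage after position i: s[i] is K/R and s[i+1] is not P
  cut_after <- which(s %in% c("K", "R") & c(s[-1], "") != "P" &
                       seq_len(n) < n)
  bounds <- c(0, cut_after, n)      # fragment boundaries
  nfrag <- length(bounds) - 1
  out <- list()
  for (i in seq_len(nfrag)) {
    for (m in 0:max_missed) {
      j <- i + m
      if (j > nfrag) break
      start <- bounds[i] + 1
      end <- bounds[j + 1]
      out[[length(out) + 1]] <- data.frame(
        chain_id = chain$chain_id, start = start, end = end,
        sequence = substr(chain$residues, start, end),
        missed_cleavages = m, stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  res <- res[!duplicated(res[, c("start", "end")]), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Define a modification
#'
#' @param name Modification name, e.g. `"Oxidation"`.
#' @param targets Character vector of target residue letters.
#' @param position_rule `"anywhere"`, `"protein_nterm"` or `"protein_cterm"`.
#' @param delta_mass Monoisotopic delta mass in Da.
#' @param formula Optional elemental composition; when given it must agree
#'   with `delta_mass` to 1e-4 Da.
#' @return A `modification_def` object.
#' @export
modification_def <- function(name, targets, delta_mass,
                             position_rule = c("anywhere", "protein_nterm",
                                               "protein_cterm"),
                             formula = NULL) {
  position_rule <- match.arg(position_rule)
  if (!is.null(formula)) {
    fm <- formula_mono_mass(formula)
    if (abs(fm - abs(delta_mass)) > 1e-4) {
      stop(sprintf("delta_mass %.5f inconsistent with formula %s (%.5f)",
                   delta_mass, formula, fm))
    }
  }
  structure(list(name = name, targets = targets, delta_mass = delta_mass,
                 position_rule = position_rule, formula = formula),
            class = "modification_def")
}

#' Default modification panel for mAb attribute monitoring
#'
#' Deamidation of N/Q, oxidation of M, dioxidation of M/W, N-terminal
#' pyroglutamate from Q or E, and C-terminal lysine loss — the standard
#' chemical-modification panel monitored in peptide-map MAM workflows.
#'
#' @return List of [modification_def()] objects.
#' @export
default_modification_panel <- function() {
  list(
    modification_def("Deamidation", c("N", "Q"), 0.984016),
    modification_def("Oxidation", "M", 15.994915),
    modification_def("Dioxidation", c("M", "W"), 31.989829),
    modification_def("PyroGluQ", "Q", -17.026549, "protein_nterm"),
    modification_def("PyroGluE", "E", -18.010565, "protein_nterm"),
    modification_def("LysLoss", "K", -128.09496, "protein_cterm")
  )
}

#' Default Fc N-glycan panel
#'
#' Oxford-notation compositions covering the common IgG1 Fc glycoforms.
#'
#' @return List of [glycan_composition()] objects.
#' @export
default_glycan_panel <- function() {
  list(
    glycan_composition("FA2", H = 3, N = 4, F = 1),
    glycan_composition("FA2G1", H = 4, N = 4, F = 1),
    glycan_composition("FA2G2", H = 5, N = 4, F = 1),
    glycan_composition("FA1", H = 3, N = 3, F = 1),
    glycan_composition("FA3", H = 3, N = 5, F = 1),
    glycan_composition("A2", H = 3, N = 4),
    glycan_composition("A1", H = 3, N = 3),
    glycan_composition("M5", H = 5, N = 2)
  )
}

#' Construct a quantification target species
#'
#' A species is one molecular form of a backbone peptide: optional site
#' modifications, optional glycan, fixed carbamidomethyl on every cysteine.
#'
#' @param peptide One row of a [digest()] data.frame (or a list with
#'   `chain_id`, `start`, `end`, `sequence`).
#' @param site_mods List of `list(position = <chain position>, mod =
#'   <modification_def>)`, possibly empty.
#' @param glycan Optional [glycan_composition()] (at most one per species).
#' @param charges Integer vector of monitored charge states.
#' @param expected_rt Optional expected apex retention time (minutes).
#' @return A `target_species` object with `neutral_mono_mass` and a stable
#'   `species_id`.
#' @export
target_species <- function(peptide, site_mods = list(), glycan = NULL,
                           charges = 2:4, expected_rt = NA_real_) {
  seq <- peptide$sequence
  n_cys <- lengths(regmatches(seq, gregexpr("C", seq)))
  deltas <- vapply(site_mods, function(sm) sm$mod$delta_mass, numeric(1))
  gl_mass <- if (!is.null(glycan)) glycan_mass(glycan) else 0
  mass <- peptide_mono_mass(seq) + n_cys * CARBAMIDOMETHYL_MONO +
    sum(deltas) + gl_mass
  mod_tag <- if (length(site_mods)) {
    paste(vapply(site_mods, function(sm)
      paste0(sm$mod$name, "@", sm$position), character(1)), collapse = "+")
  } else "unmodified"
  gl_tag <- if (!is.null(glycan)) glycan$oxford_name else ""
  id <- paste0(peptide$chain_id, ":", peptide$start, "-", peptide$end, "/",
               mod_tag, if (nzchar(gl_tag)) paste0("/", gl_tag) else "")
  structure(
    list(species_id = id, peptide = as.list(peptide), site_mods = site_mods,
         glycan = glycan, neutral_mono_mass = mass,
         charges = as.integer(charges), expected_rt = expected_rt),
    class = "target_species"
  )
}

#' @export
print.target_species <- function(x, ...) {
  cat(sprintf("<species %s, %0.5f Da, z=%s>\n", x$species_id,
              x$neutral_mono_mass, paste(x$charges, collapse = ",")))
  invisible(x)
}

#' Enumerate the PQA panel for a set of chains
#'
#' Scans every fully cleaved tryptic backbone peptide for eligible
#' modification sites and builds one PQA definition per site: the modified
#' species plus the complement of all panel forms of the same backbone, so
#' the relative-abundance denominator contains every form exactly once.
#' N-terminal pyroglutamate applies only to chain position 1 (Q or E);
#' lysine loss only to the chain C-terminal K. When `glyco_sites` are given
#' (validated against the N-X-S/T sequon), one glycoform PQA is built per
#' site from `glycans` plus the aglycosylated peptide.
#'
#' @param chains List of [chain_sequence()] objects.
#' @param modifications List of [modification_def()], default
#'   [default_modification_panel()].
#' @param glycans Optional list of [glycan_composition()] for glyco sites.
#' @param glyco_sites Optional list of `list(chain_id =, position =)` giving
#'   N-glycosylation sites.
#' @param max_missed Missed cleavages for the digest (default 1).
#' @param charges Monitored charge states per species.
#' @return List of `pqa_definition` objects, each with `pqa_id`, `site`,
#'   `modification` (or `glycans`), `modified_species`, `all_species`.
#' @export
enumerate_pqa_species <- function(chains,
                                  modifications = default_modification_panel(),
                                  glycans = NULL, glyco_sites = NULL,
                                  max_missed = 1, charges = 2:4) {
  peptides <- lapply(chains, digest, max_missed = max_missed)
  backbones <- lapply(seq_along(chains), function(i) {
    p <- peptides[[i]]
    p[p$missed_cleavages == 0, , drop = FALSE]
  })

  # per backbone peptide, collect eligible (site, mod) pairs
  site_table <- list()
  for (ci in seq_along(chains)) {
    chain <- chains[[ci]]
    letters <- strsplit(chain$residues, "")[[1]]
    bb <- backbones[[ci]]
    for (mod in modifications) {
      pos <- which(letters %in% mod$targets)
      pos <- switch(mod$position_rule,
        anywhere = pos,
        protein_nterm = pos[pos == 1],
        protein_cterm = pos[pos == length(letters)]
      )
      if (!length(pos)) {
        warning("modification '", mod$name, "' targets no residue on ",
                chain$chain_id, " chain; skipped")
        next
      }
      for (p in pos) {
        row <- which(bb$start <= p & bb$end >= p)
        if (!length(row)) next
        site_table[[length(site_table) + 1]] <- list(
          chain = ci, position = p, mod = mod, bb_row = row[1]
        )
      }
    }
  }

  defs <- list()
  counters <- new.env(parent = emptyenv())
  for (entry in site_table) {
    chain <- chains[[entry$chain]]
    pep <- backbones[[entry$chain]][entry$bb_row, ]
    k <- (get0(entry$mod$name, counters, ifnotfound = 0)) + 1
    assign(entry$mod$name, k, counters)
    pqa_id <- paste0(entry$mod$name, "_", k)
    modified <- target_species(pep,
      site_mods = list(list(position = entry$position, mod = entry$mod)),
      charges = charges)
    # complement: every panel form of this backbone = unmodified + each
    # single-site single-mod form
    siblings <- Filter(function(e) e$chain == entry$chain &&
                         e$bb_row == entry$bb_row, site_table)
    all_sp <- c(list(target_species(pep, charges = charges)),
                lapply(siblings, function(e)
                  target_species(pep,
                    site_mods = list(list(position = e$position, mod = e$mod)),
                    charges = charges)))
    defs[[length(defs) + 1]] <- structure(
      list(pqa_id = pqa_id,
           site = list(chain_id = chain$chain_id, position = entry$position),
           modification = entry$mod,
           modified_species = list(modified),
           all_species = all_sp),
      class = "pqa_definition"
    )
  }

  if (!is.null(glyco_sites)) {
    if (is.null(glycans)) stop("glyco_sites given without a glycan panel")
    gk <- 0
    for (gs in glyco_sites) {
      ci <- which(vapply(chains, function(ch) ch$chain_id == gs$chain_id,
                         logical(1)))[1]
      if (is.na(ci)) stop("glyco site on unknown chain ", gs$chain_id)
      chain <- chains[[ci]]
      letters <- strsplit(chain$residues, "")[[1]]
      p <- gs$position
      ok <- p + 2 <= length(letters) && letters[p] == "N" &&
        letters[p + 1] != "P" && letters[p + 2] %in% c("S", "T")
      if (!ok) stop("position ", p, " on ", gs$chain_id,
                    " chain is not an N-X-S/T sequon")
      bb <- backbones[[ci]]
      row <- which(bb$start <= p & bb$end >= p)[1]
      pep <- bb[row, ]
      gk <- gk + 1
      glyco_species <- lapply(glycans, function(g)
        target_species(pep, glycan = g, charges = charges,
                       site_mods = list()))
      aglyco <- target_species(pep, charges = charges)
      defs[[length(defs) + 1]] <- structure(
        list(pqa_id = paste0("Glycoforms_", gk),
             site = list(chain_id = gs$chain_id, position = p),
             glycans = glycans,
             modified_species = glyco_species,
             all_species = c(glyco_species, list(aglyco))),
        class = "pqa_definition"
      )
    }
  }

  ids <- vapply(defs, function(d) d$pqa_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate pqa_id: ", ids[duplicated(ids)][1])
  defs
}

#' @export
print.pqa_definition <- function(x, ...) {
  cat(sprintf("<PQA %s @ %s chain pos %d: %d modified / %d total species>\n",
              x$pqa_id, x$site$chain_id, x$site$position,
              length(x$modified_species), length(x$all_species)))
  invisible(x)
}

#' Theoretical b/y fragment ions
#'
#' All b and y ions of a target species at charges `1..max_charge`, with
#' site-modification (and glycan) deltas applied to the fragments containing
#' the modified residue. Fixed carbamidomethyl is applied per fragment
#' cysteine.
#'
#' @param species A [target_species()].
#' @param max_charge Maximum fragment charge (default 1).
#' @return data.frame with columns `series` ("b"/"y"), `index`, `charge`,
#'   `mz`.
#' @export
fragment_ions <- function(species, max_charge = 1) {
  seq <- species$peptide$sequence
  n <- nchar(seq)
  if (n < 2) stop("peptide must have length >= 2")
  letters <- strsplit(seq, "")[[1]]
  res <- AA_MONO[letters]
  res[letters == "C"] <- res[letters == "C"] + CARBAMIDOMETHYL_MONO
  # per-residue modification deltas at peptide-relative positions
  deltas <- numeric(n)
  for (sm in species$site_mods) {
    rel <- sm$position - species$peptide$start + 1
    if (rel >= 1 && rel <= n) deltas[rel] <- deltas[rel] + sm$mod$delta_mass
  }
  if (!is.null(species$glycan)) {
    # attach the glycan to the first N of the sequon, else the first residue
    gpos <- regexpr("N[^P][ST]", seq)
    gpos <- if (gpos > 0) gpos else 1L
    deltas[gpos] <- deltas[gpos] + glycan_mass(species$glycan)
  }
  cum <- cumsum(res + deltas)
  total <- cum[n]
  out <- list()
  for (z in seq_len(max_charge)) {
    for (i in seq_len(n - 1)) {
      b_mass <- cum[i]                      # b ion: residues 1..i
      y_mass <- total - cum[n - i] + WATER_MONO  # y ion: last i residues
      out[[length(out) + 1]] <- data.frame(
        series = c("b", "y"), index = i, charge = z,
        mz = c((b_mass + z * PROTON_MASS) / z,
               (y_mass + z * PROTON_MASS) / z)
      )
    }
  }
  res_df <- do.call(rbind, out)
  rownames(res_df) <- NULL
  res_df
}
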