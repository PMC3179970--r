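## Tolerant fixed-column PDB reading.
##
## Docking decoys frequently carry malformed bookkeeping columns
## (occupancy, B-factor, element), so only the columns that matter are
## read: atom name, altloc, residue name/number, chain and coordinates.
## Only the first MODEL is kept, altloc blank or 'A' is accepted, waters
## and non-polymer HETATM groups are dropped, and hydrogens are ignored
## throughout (all derived quantities use heavy atoms only).

.water_codes <- c("HOH", "WAT", "DOD", "H2O", "SOL")

.infer_element <- function(name) {
  core <- gsub("[^A-Za-z]", "", name)
  ifelse(nchar(core) == 0L, "X", toupper(substr(core, 1L, 1L)))
}

#' Parse PDB-format text into a structure object
#'
#' Reads ATOM/HETATM records from fixed columns, keeping only the first
#' MODEL and altloc blank/'A' atoms.  Occupancy, B-factor and other
#' bookkeeping columns are ignored entirely, so garbled values there do
#' not affect parsing.  Waters, hydrogens and HETATM groups without
#' polymer backbone atoms (CA, C1' or P) are excluded.  Chains are
#' classified as protein or RNA by an atom census, and modified
#' nucleotides are mapped to their canonical parent base (MODRES records,
#' when present, override the census-based fallback for unknown codes).
#'
#' @param text Character scalar (possibly multi-line) or vector of lines.
#' @param source_id Free-text provenance label stored on the result.
#' @return An object of class `rnp_structure`: a list of chains, each with
#'   an `id`, a `kind` (`"protein"`, `"rna"` or `"other"`) and a list of
#'   residues carrying canonical `code`, `raw_code`, `is_modified` and an
#'   atom table (`name`, `element`, `x`, `y`, `z`).
#' @seealso [read_pdb()], [write_pdb()]
#' @export
parse_pdb <- function(text, source_id = "pdb") {
  lines <- if (length(text) == 1L && grepl("\n", text, fixed = TRUE))
    strsplit(text, "\n", fixed = TRUE)[[1]] else text
  if (length(lines) == 0L)
    stop("empty PDB input: no records at all", call. = FALSE)
  rec <- substr(lines, 1L, 6L)

  # first model only
  model_starts <- which(trimws(rec) == "MODEL")
  if (length(model_starts) >= 2L)
    lines <- lines[seq_len(model_starts[2L] - 1L)]
  endmdl <- which(substr(lines, 1L, 6L) == "ENDMDL")
  if (length(endmdl) >= 1L)
    lines <- lines[seq_len(endmdl[1L] - 1L)]
  rec <- substr(lines, 1L, 6L)

  # MODRES: residue code (13-15), chain (17), seq (19-22), parent (25-27)
  modres_map <- character(0)
  for (ln in lines[rec == "MODRES"]) {
    key <- paste(substr(ln, 17L, 17L), trimws(substr(ln, 19L, 22L)),
                 toupper(trimws(substr(ln, 13L, 15L))), sep = "|")
    modres_map[key] <- toupper(trimws(substr(ln, 25L, 27L)))
  }

  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom))
    stop("no ATOM or HETATM records found in PDB input", call. = FALSE)
  al <- lines[is_atom]
  hetero <- rec[is_atom] == "HETATM"

  name <- trimws(substr(al, 13L, 16L))
  altloc <- substr(al, 17L, 17L)
  resname <- toupper(trimws(substr(al, 18L, 20L)))
  chain <- substr(al, 22L, 22L)
  resseq <- trimws(substr(al, 23L, 26L))
  icode <- substr(al, 27L, 27L)
  x <- suppressWarnings(as.numeric(substr(al, 31L, 38L)))
  y <- suppressWarnings(as.numeric(substr(al, 39L, 46L)))
  z <- suppressWarnings(as.numeric(substr(al, 47L, 54L)))
  element <- toupper(trimws(substr(al, 77L, 78L)))
  element <- ifelse(element == "" | is.na(element), .infer_element(name),
                    element)
  # PDBv2-style names such as " 1H5'" put digits first
  element[grepl("^[0-9]", name) & element %in% c("1", "2", "3")] <-
    .infer_element(name[grepl("^[0-9]", name) & element %in% c("1", "2", "3")])

  keep <- (altloc %in% c(" ", "A", "")) &
    !(element %in% c("H", "D")) &
    !(resname %in% .water_codes) &
    is.finite(x) & is.finite(y) & is.finite(z)
  if (!any(keep))
    stop("PDB input contains no usable heavy-atom records", call. = FALSE)
  name <- name[keep]; resname <- resname[keep]; chain <- chain[keep]
  resseq <- resseq[keep]; icode <- icode[keep]; hetero <- hetero[keep]
  element <- element[keep]; x <- x[keep]; y <- y[keep]; z <- z[keep]

  res_key <- paste(chain, resseq, icode, resname, sep = "|")
  res_order <- unique(res_key)
  chains <- list()
  for (rk in res_order) {
    sel <- which(res_key == rk)
    atoms <- data.frame(name = name[sel], element = element[sel],
                        x = x[sel], y = y[sel], z = z[sel],
                        hetero = hetero[sel], stringsAsFactors = FALSE)
    # drop non-polymer HETATM groups (ions, cofactors): no backbone anchor
    if (all(atoms$hetero) &&
        !any(c("CA", "C1'", "P") %in% atoms$name)) next
    cid <- chain[sel[1L]]
    residue <- list(raw_code = resname[sel[1L]], code = resname[sel[1L]],
                    chain = cid, seq = resseq[sel[1L]],
                    icode = icode[sel[1L]], is_modified = FALSE,
                    kind = "other", atoms = atoms)
    chains[[cid]] <- c(chains[[cid]], list(residue))
  }
  if (length(chains) == 0L)
    stop("PDB input has no polymer residues after filtering", call. = FALSE)

  chains <- lapply(chains, function(res_list) {
    kind <- classify_chain(res_list)
    res_list <- lapply(res_list, function(r) {
      r$kind <- kind
      if (kind == "rna") {
        key <- paste(r$chain, r$seq, r$raw_code, sep = "|")
        m <- map_modified_residue(r$raw_code, r$atoms$name,
                                  modres = modres_map[key])
        r$code <- m$code
        r$is_modified <- m$is_modified
      } else if (kind == "protein") {
        if (r$raw_code == "MSE") { r$code <- "MET"; r$is_modified <- TRUE }
      }
      r
    })
    list(id = res_list[[1L]]$chain, kind = kind, residues = res_list)
  })
  structure(list(source_id = source_id, chains = chains),
            class = "rnp_structure")
}

#' Read a PDB file
#'
#' @param file Path to a PDB file.
#' @param source_id Provenance label; defaults to the file name.
#' @return An `rnp_structure`; see [parse_pdb()].
#' @export
read_pdb <- function(file, source_id = basename(file)) {
  parse_pdb(readLines(file, warn = FALSE), source_id = source_id)
}

#' Classify a chain as protein, RNA or other
#'
#' Decided by an atom census over the chain's residues: protein when at
#' least 90 percent of residues carry a CA atom; RNA when at least 90
#' percent carry a C1' atom, or a P atom together with ribose atoms;
#' anything else (including mixed chains) is `"other"`.
#'
#' @param residues List of residue records (as built by [parse_pdb()]).
#' @return One of `"protein"`, `"rna"`, `"other"`.
#' @export
classify_chain <- function(residues) {
  stopifnot(length(residues) > 0L)
  has_ca <- vapply(residues, function(r) "CA" %in% r$atoms$name, logical(1))
  has_nt <- vapply(residues, function(r) {
    nm <- r$atoms$name
    ("C1'" %in% nm) || ("P" %in% nm && any(.rna_ribose %in% nm))
  }, logical(1))
  if (mean(has_ca) >= 0.9) "protein"
  else if (mean(has_nt) >= 0.9) "rna"
  else "other"
}

#' Write a structure as minimal PDB text
#'
#' Fixture-grade writer emitting one ATOM record per heavy atom with
#' standard fixed columns (occupancy 1.00, B-factor 0.00).
#'
#' @param structure An `rnp_structure`.
#' @param file Optional path; when `NULL` the text is returned invisibly.
#' @return The PDB lines, invisibly.
#' @export
write_pdb <- function(structure, file = NULL) {
  stopifnot(inherits(structure, "rnp_structure"))
  out <- character(0)
  serial <- 0L
  for (ch in structure$chains) {
    for (r in ch$residues) {
      resnm <- if (ch$kind == "rna") r$raw_code else r$raw_code
      for (k in seq_len(nrow(r$atoms))) {
        serial <- serial + 1L
        nm <- r$atoms$name[k]
        # column-13 alignment: 1-3 char names start in column 14
        nm_fmt <- if (nchar(nm) >= 4L) substr(nm, 1L, 4L)
                  else sprintf(" %-3s", nm)
        out <- c(out, sprintf(
          "ATOM  %5d %s%s%3s %s%4s%s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial %% 100000L, nm_fmt, " ", substr(resnm, 1L, 3L), ch$id,
          substr(r$seq, 1L, 4L),
          if (nzchar(trimws(r$icode))) r$icode else " ",
          r$atoms$x[k], r$atoms$y[k], r$atoms$z[k], 1, 0,
          r$atoms$element[k]))
      }
    }
    out <- c(out, "TER")
  }
  out <- c(out, "END")
  if (!is.null(file)) writeLines(out, file)
  invisible(out)
}

#' @export
print.rnp_structure <- function(x, ...) {
  cat("Protein-RNA structure: ", x$source_id, "\n", sep = "")
  for (ch in x$chains) {
    natm <- sum(vapply(ch$residues, function(r) nrow(r$atoms), integer(1)))
    nmod <- sum(vapply(ch$residues, function(r) isTRUE(r$is_modified),
                       logical(1)))
    cat(sprintf("  chain %s: %-7s %4d residues, %5d heavy atoms%s\n",
                ch$id, ch$kind, length(ch$residues), natm,
                if (nmod > 0) sprintf(" (%d modified)", nmod) else ""))
  }
  invisible(x)
}
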