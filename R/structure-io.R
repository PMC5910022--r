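#' Tidy atomic structures
#'
#' A structure is an ordered tibble of atom records (one row per atom) with
#' columns `serial`, `name`, `element`, `alt_loc`, `res_name`, `chain_id`,
#' `res_seq` (author numbering), `i_code`, `x`, `y`, `z` (Angstrom),
#' `occupancy`, `b_factor` (Angstrom^2), `mass` (Da), `is_hetero`.
#' Row order is file order and is preserved by all selections.
#'
#' @param atoms A data frame with at least `name`, `element`, `chain_id`,
#'   `res_seq`, `x`, `y`, `z` columns; missing bookkeeping columns are filled
#'   with defaults.
#' @param model_id Integer model number.
#' @param source_id Free-text provenance label (e.g. a PDB accession or path).
#' @return A `conf_structure` tibble.
#' @export
as_structure <- function(atoms, model_id = 1L, source_id = "") {
  atoms <- tibble::as_tibble(atoms)
  n <- nrow(atoms)
  defaults <- list(
    serial = seq_len(n), alt_loc = "", res_name = "UNK", i_code = "",
    occupancy = 1, b_factor = 0, is_hetero = FALSE
  )
  for (col in names(defaults)) {
    if (!col %in% names(atoms)) atoms[[col]] <- rep(defaults[[col]], length.out = n)
  }
  required <- c("name", "element", "chain_id", "res_seq", "x", "y", "z")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0) {
    abort_input(paste0("atom table lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (!"mass" %in% names(atoms)) atoms$mass <- element_mass(atoms$element)
  atoms$res_seq <- as.integer(atoms$res_seq)
  atoms$serial <- as.integer(atoms$serial)
  atoms <- atoms[, c(
    "serial", "name", "element", "alt_loc", "res_name", "chain_id",
    "res_seq", "i_code", "x", "y", "z", "occupancy", "b_factor",
    "mass", "is_hetero"
  )]
  validate_structure(atoms)
  structure(atoms,
    class = c("conf_structure", class(tibble::tibble())),
    model_id = as.integer(model_id), source_id = source_id
  )
}

validate_structure <- function(atoms) {
  if (nrow(atoms) == 0) return(invisible(atoms))
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) abort_input("non-finite atom coordinates")
  if (any(atoms$occupancy < 0 | atoms$occupancy > 1)) {
    abort_input("occupancy outside [0, 1]")
  }
  if (any(atoms$b_factor < 0)) abort_input("negative B factor")
  key <- paste(atoms$chain_id, atoms$res_seq, atoms$i_code, atoms$name, atoms$alt_loc)
  if (anyDuplicated(key)) {
    abort_input("duplicate atom identity (chain, res_seq, i_code, name, alt_loc)")
  }
  invisible(atoms)
}

#' @export
print.conf_structure <- function(x, ...) {
  cat(sprintf(
    "# conf_structure: %d atoms, %d chain(s), source '%s'\n",
    nrow(x), length(unique(x$chain_id)), attr(x, "source_id") %||% ""
  ))
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

structure_source <- function(s) attr(s, "source_id") %||% ""

#' Read an atomic coordinate file
#'
#' Parses PDB (fixed-column ATOM/HETATM records) or mmCIF (`atom_site` loop)
#' files into a tidy structure. Heteroatoms are retained and flagged through
#' `is_hetero`/`res_name`; waters (HOH/WAT/DOD) are excluded by default.
#' Only the requested model is returned (the first, by default).
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"pdb"` or `"mmcif"`.
#' @param model Model number to keep; `NULL` keeps the first model present.
#' @param keep_waters Retain water residues?
#' @return A `conf_structure` tibble.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           model = NULL, keep_waters = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) abort_input(paste0("file not found: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  atoms <- switch(format,
    pdb = parse_pdb(readLines(path, warn = FALSE), path),
    mmcif = parse_mmcif(readLines(path, warn = FALSE), path)
  )
  if (nrow(atoms) == 0) abort_input(paste0("no atom records found in ", path))
  keep_model <- if (is.null(model)) atoms$model_id[1] else as.integer(model)
  atoms <- atoms[atoms$model_id == keep_model, , drop = FALSE]
  if (nrow(atoms) == 0) abort_input(sprintf("model %d not present in %s", keep_model, path))
  if (!keep_waters) {
    atoms <- atoms[!toupper(atoms$res_name) %in% c("HOH", "WAT", "DOD"), , drop = FALSE]
  }
  atoms$model_id <- NULL
  as_structure(atoms, model_id = keep_model, source_id = path)
}

parse_pdb <- function(lines, path) {
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  model_starts <- which(trimws(rec) == "MODEL")
  model_of_line <- rep(1L, length(lines))
  if (length(model_starts) > 0) {
    model_no <- suppressWarnings(as.integer(substr(lines[model_starts], 7, 80)))
    model_no[is.na(model_no)] <- seq_along(model_starts)[is.na(model_no)]
    idx <- findInterval(seq_along(lines), model_starts)
    model_of_line <- ifelse(idx == 0, 1L, model_no[pmax(idx, 1L)])
  }
  lines_a <- lines[is_atom]
  if (length(lines_a) == 0) return(tibble::tibble())
  fw <- function(l, a, b) substr(l, a, b)
  num <- function(txt, what) {
    out <- suppressWarnings(as.numeric(txt))
    if (any(is.na(out) & nzchar(trimws(txt)))) {
      bad <- which(is.na(out) & nzchar(trimws(txt)))[1]
      abort_input(sprintf(
        "cannot parse %s in PDB record %d of %s: '%s'",
        what, bad, path, trimws(txt[bad])
      ))
    }
    out
  }
  element <- trimws(fw(lines_a, 77, 78))
  name <- trimws(fw(lines_a, 13, 16))
  # fall back to the atom-name convention when the element field is blank
  guess <- sub("^[0-9]*", "", name)
  guess2 <- toupper(substr(guess, 1, 2))
  guess1 <- toupper(substr(guess, 1, 1))
  element <- ifelse(
    nzchar(element), element,
    ifelse(guess2 %in% names(.element_masses) &
             !guess1 %in% c("C", "N", "O", "S", "P", "H"), guess2, guess1)
  )
  occ <- num(fw(lines_a, 55, 60), "occupancy")
  occ[is.na(occ)] <- 1
  bf <- num(fw(lines_a, 61, 66), "B factor")
  bf[is.na(bf)] <- 0
  tibble::tibble(
    serial = as.integer(num(fw(lines_a, 7, 11), "serial")),
    name = name,
    element = element,
    alt_loc = trimws(fw(lines_a, 17, 17)),
    res_name = trimws(fw(lines_a, 18, 20)),
    chain_id = trimws(fw(lines_a, 22, 22)),
    res_seq = as.integer(num(fw(lines_a, 23, 26), "residue number")),
    i_code = trimws(fw(lines_a, 27, 27)),
    x = num(fw(lines_a, 31, 38), "x coordinate"),
    y = num(fw(lines_a, 39, 46), "y coordinate"),
    z = num(fw(lines_a, 47, 54), "z coordinate"),
    occupancy = occ,
    b_factor = bf,
    is_hetero = rec[is_atom] == "HETATM",
    model_id = model_of_line[is_atom]
  )
}

# minimal tokenizer for mmCIF data rows: space-separated with '...' / "..."
cif_tokens <- function(line) {
  toks <- regmatches(line, gregexpr("'[^']*'|\"[^\"]*\"|\\S+", line))[[1]]
  gsub("^['\"]|['\"]$", "", toks)
}

parse_mmcif <- function(lines, path) {
  lines <- lines[!grepl("^\\s*#", lines)]
  field_idx <- grep("^_atom_site\\.", lines)
  if (length(field_idx) == 0) abort_input(paste0("no _atom_site loop in ", path))
  fields <- sub("^_atom_site\\.", "", trimws(lines[field_idx]))
  data_start <- max(field_idx) + 1
  rows <- character()
  for (i in data_start:length(lines)) {
    l <- trimws(lines[i])
    if (l == "" || startsWith(l, "_") || startsWith(l, "loop_") ||
        startsWith(l, "data_") || l == "#") break
    rows <- c(rows, l)
  }
  if (length(rows) == 0) abort_input(paste0("empty _atom_site loop in ", path))
  tok <- lapply(rows, cif_tokens)
  nf <- length(fields)
  bad <- which(vapply(tok, length, 1L) != nf)
  if (length(bad) > 0) {
    abort_input(sprintf(
      "mmCIF atom_site row %d of %s has %d fields, expected %d",
      bad[1], path, length(tok[[bad[1]]]), nf
    ))
  }
  m <- do.call(rbind, tok)
  colnames(m) <- fields
  get <- function(nm, default = NA_character_) {
    if (nm %in% fields) m[, nm] else rep(default, nrow(m))
  }
  dot_na <- function(v) ifelse(v %in% c(".", "?"), "", v)
  num_or <- function(v, default) {
    out <- suppressWarnings(as.numeric(dot_na(v)))
    out[is.na(out)] <- default
    out
  }
  res_seq <- suppressWarnings(as.integer(dot_na(get("auth_seq_id", get("label_seq_id")))))
  if (any(is.na(res_seq))) abort_input(paste0("unparseable residue numbers in ", path))
  tibble::tibble(
    serial = as.integer(num_or(get("id"), seq_len(nrow(m)))),
    name = dot_na(get("auth_atom_id", get("label_atom_id"))),
    element = dot_na(get("type_symbol")),
    alt_loc = dot_na(get("label_alt_id")),
    res_name = dot_na(get("auth_comp_id", get("label_comp_id"))),
    chain_id = dot_na(get("auth_asym_id", get("label_asym_id"))),
    res_seq = res_seq,
    i_code = dot_na(get("pdbx_PDB_ins_code")),
    x = as.numeric(get("Cartn_x")),
    y = as.numeric(get("Cartn_y")),
    z = as.numeric(get("Cartn_z")),
    occupancy = num_or(get("occupancy"), 1),
    b_factor = num_or(get("B_iso_or_equiv"), 0),
    is_hetero = toupper(get("group_PDB", "ATOM")) == "HETATM",
    model_id = as.integer(num_or(get("pdbx_PDB_model_num"), 1L))
  )
}

#' Write a structure to PDB or mmCIF
#'
#' Coordinates are stored to 3 decimals and occupancies/B factors to
#' 2 decimals in the PDB dialect (format precision); mmCIF keeps the same
#' rounding for round-trip equality between the two dialects.
#'
#' @param structure A `conf_structure`.
#' @param path Output path.
#' @param format `"auto"` (by extension), `"pdb"` or `"mmcif"`.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (nrow(structure) == 0) abort_input("refusing to write an empty structure")
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  lines <- switch(format,
    pdb = format_pdb(structure),
    mmcif = format_mmcif(structure)
  )
  ok <- tryCatch({ writeLines(lines, path); TRUE }, error = function(e) FALSE)
  if (!ok) abort_input(paste0("cannot write to ", path))
  invisible(path)
}

format_pdb <- function(s) {
  rec <- ifelse(s$is_hetero, "HETATM", "ATOM  ")
  # PDB atom-name column convention: 1/2-char element names start in col 14
  name <- ifelse(
    nchar(s$name) >= 4, substr(s$name, 1, 4),
    ifelse(nchar(s$element) == 2, sprintf("%-4s", s$name), sprintf(" %-3s", s$name))
  )
  body <- sprintf(
    "%s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    rec, s$serial %% 100000L, name, substr(s$alt_loc, 1, 1),
    substr(s$res_name, 1, 3), substr(s$chain_id, 1, 1), s$res_seq %% 10000L,
    substr(s$i_code, 1, 1), s$x, s$y, s$z, s$occupancy, s$b_factor,
    toupper(s$element)
  )
  c(body, "END")
}

format_mmcif <- function(s) {
  q <- function(v) ifelse(v == "", ".", v)
  rows <- sprintf(
    "%s %d %s %s %s %s %s %d %s %.3f %.3f %.3f %.2f %.2f 1",
    ifelse(s$is_hetero, "HETATM", "ATOM"), s$serial, toupper(s$element),
    q(s$name), q(s$alt_loc), q(s$res_name), q(s$chain_id), s$res_seq,
    q(s$i_code), s$x, s$y, s$z, s$occupancy, s$b_factor
  )
  c(
    "data_conformeter",
    "#", "loop_",
    paste0("_atom_site.", c(
      "group_PDB", "id", "type_symbol", "auth_atom_id", "label_alt_id",
      "auth_comp_id", "auth_asym_id", "auth_seq_id", "pdbx_PDB_ins_code",
      "Cartn_x", "Cartn_y", "Cartn_z", "occupancy", "B_iso_or_equiv",
      "pdbx_PDB_model_num"
    )),
    rows, "#"
  )
}

#' Select atoms belonging to a domain
#'
#' Keeps atoms whose `(chain_id, res_seq)` falls inside the domain's residue
#' ranges, preserving file order. Hydrogens are dropped when `heavy_only`,
#' and exactly one alternate location is kept per atom according to
#' `altloc_policy`. An empty result is an error, never a silent empty table.
#'
#' @param structure A `conf_structure`.
#' @param domain A domain definition tibble (see [domain_definition()]).
#' @param heavy_only Drop hydrogens/deuteriums?
#' @param altloc_policy `"highest_occupancy"` (ties broken by altloc label)
#'   or `"first"` (file order).
#' @return A `conf_structure` tibble.
#' @export
select_domain <- function(structure, domain, heavy_only = TRUE,
                          altloc_policy = c("highest_occupancy", "first")) {
  altloc_policy <- match.arg(altloc_policy)
  stopifnot(is.data.frame(domain))
  chains <- unique(domain$chain_id)
  missing_chain <- setdiff(chains, unique(structure$chain_id))
  if (length(missing_chain) > 0) {
    abort_input(paste0("chain(s) not present in structure: ",
                       paste(missing_chain, collapse = ", ")))
  }
  keep <- rep(FALSE, nrow(structure))
  for (i in seq_len(nrow(domain))) {
    keep <- keep | (structure$chain_id == domain$chain_id[i] &
                      structure$res_seq >= domain$start[i] &
                      structure$res_seq <= domain$end[i])
  }
  out <- structure[keep, , drop = FALSE]
  if (heavy_only) out <- out[!toupper(out$element) %in% c("H", "D"), , drop = FALSE]
  if (nrow(out) > 0 && any(out$alt_loc != "")) {
    atom_key <- paste(out$chain_id, out$res_seq, out$i_code, out$name)
    ord <- seq_len(nrow(out))
    pick <- if (altloc_policy == "highest_occupancy") {
      order(atom_key, -out$occupancy, out$alt_loc, ord)
    } else {
      order(atom_key, ord)
    }
    first_of_key <- !duplicated(atom_key[pick])
    out <- out[sort(pick[first_of_key]), , drop = FALSE]
  }
  if (nrow(out) == 0) {
    abort_input(sprintf(
      "empty selection: domain '%s' matches no atoms",
      paste(unique(domain$name), collapse = ",")
    ))
  }
  as_structure(out,
    model_id = attr(structure, "model_id") %||% 1L,
    source_id = structure_source(structure)
  )
}

#' Residue-range domain definitions
#'
#' A domain definition is a tibble with one row per residue interval:
#' columns `name`, `chain_id`, `start`, `end` (1-based, inclusive, author
#' numbering). Intervals within one definition must not overlap.
#'
#' @param name Domain label (e.g. `"D1"`, `"IDE-N"`, `"door"`).
#' @param chain_id Chain identifier.
#' @param ranges A list of `c(start, end)` integer pairs.
#' @return A domain-definition tibble.
#' @export
#' @examples
#' domain_definition("door", "A", list(c(170, 237)))
domain_definition <- function(name, chain_id, ranges) {
  if (is.numeric(ranges)) ranges <- list(ranges)
  df <- tibble::tibble(
    name = name, chain_id = chain_id,
    start = vapply(ranges, function(r) as.integer(r[1]), 1L),
    end = vapply(ranges, function(r) as.integer(r[2]), 1L)
  )
  if (any(df$end < df$start)) abort_config("domain interval with end < start")
  df_ord <- df[order(df$start), ]
  if (nrow(df_ord) > 1 && any(df_ord$start[-1] <= df_ord$end[-nrow(df_ord)])) {
    abort_config(sprintf("overlapping intervals in domain '%s'", name))
  }
  df
}

#' Default IDE domain partition
#'
#' Residue bounds for the four homologous domains of insulin-degrading
#' enzyme and the derived N/C halves and door subdomain, following the
#' conventional bounds from the IDE structural literature: D1 43-285,
#' D2 286-515, D3 542-768, D4 769-1016; IDE-N = D1+D2, IDE-C = D3+D4;
#' door 170-237. All bounds are user-overridable.
#'
#' @param chain_id Chain to attach the partition to.
#' @param bounds Named list overriding any of `d1, d2, d3, d4, door`
#'   with `c(start, end)` pairs.
#' @return A single tibble stacking the seven domain definitions.
#' @export
ide_domains <- function(chain_id = "A", bounds = list()) {
  b <- list(
    d1 = c(43L, 285L), d2 = c(286L, 515L), d3 = c(542L, 768L),
    d4 = c(769L, 1016L), door = c(170L, 237L)
  )
  b[names(bounds)] <- bounds
  dplyr::bind_rows(
    domain_definition("D1", chain_id, list(b$d1)),
    domain_definition("D2", chain_id, list(b$d2)),
    domain_definition("D3", chain_id, list(b$d3)),
    domain_definition("D4", chain_id, list(b$d4)),
    domain_definition("IDE-N", chain_id, list(b$d1, b$d2)),
    domain_definition("IDE-C", chain_id, list(b$d3, b$d4)),
    domain_definition("door", chain_id, list(b$door))
  )
}

domain_by_name <- function(domains, name) {
  d <- domains[domains$name == name, , drop = FALSE]
  if (nrow(d) == 0) abort_config(paste0("no domain named '", name, "'"))
  d
}
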