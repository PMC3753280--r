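# Minimal structure readers: fixed-width PDB ATOM/HETATM records and the
# _atom_site loop of mmCIF. Only the fields this pipeline consumes are
# retained; the first model and altloc ''/A are kept; atom-name dialects
# are normalized (C1* -> C1').

normalize_atom_name <- function(x) {
  x <- gsub("*", "'", x, fixed = TRUE)
  gsub('"', "", trimws(x))
}

normalize_resname <- function(x) {
  x <- trimws(x)
  # strip DNA/modified prefixes seen in the wild: DA, RA, A, ADE ...
  map <- c(A = "A", G = "G", C = "C", U = "U", T = "U",
           DA = "A", DG = "G", DC = "C", DT = "U", DU = "U",
           RA = "A", RG = "G", RC = "C", RU = "U",
           ADE = "A", GUA = "G", CYT = "C", URA = "U", URI = "U")
  out <- unname(map[x])
  ifelse(is.na(out), x, out)
}

#' Read atomic coordinates from a PDB or mmCIF file
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"pdb"` or `"cif"`.
#' @return Data frame of class `atom_table` with columns `chain`, `resnum`,
#'   `icode`, `resname`, `atom`, `x`, `y`, `z`. Only the lowest-numbered
#'   model and altloc ''/A records are kept.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE))
      "cif" else "pdb"
  lines <- readLines(path, warn = FALSE)
  at <- if (format == "pdb") parse_pdb_lines(lines) else parse_cif_lines(lines)
  if (!nrow(at)) stop("no atom records found in ", path)
  if (any(!is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z)))
    stop("non-finite coordinates in ", path)
  at$atom <- normalize_atom_name(at$atom)
  at$resname <- normalize_resname(at$resname)
  class(at) <- c("atom_table", "data.frame")
  at
}

parse_pdb_lines <- function(lines) {
  model <- 0L
  seen_model <- FALSE
  keep <- character(0)
  for (ln in lines) {
    tag <- substr(ln, 1L, 6L)
    if (startsWith(tag, "MODEL")) {
      model <- model + 1L
      seen_model <- TRUE
      if (model > 1L) break
    } else if (tag == "ATOM  " || tag == "HETATM") {
      keep <- c(keep, ln)
    } else if (startsWith(tag, "ENDMDL") && seen_model) {
      break
    }
  }
  if (!length(keep))
    return(data.frame(chain = character(0), resnum = integer(0),
                      icode = character(0), resname = character(0),
                      atom = character(0), x = double(0), y = double(0),
                      z = double(0)))
  altloc <- trimws(substr(keep, 17L, 17L))
  ok <- altloc %in% c("", "A")
  keep <- keep[ok]
  data.frame(
    chain = trimws(substr(keep, 21L, 22L)),
    resnum = as.integer(trimws(substr(keep, 23L, 26L))),
    icode = trimws(substr(keep, 27L, 27L)),
    resname = trimws(substr(keep, 18L, 20L)),
    atom = trimws(substr(keep, 13L, 16L)),
    x = as.numeric(substr(keep, 31L, 38L)),
    y = as.numeric(substr(keep, 39L, 46L)),
    z = as.numeric(substr(keep, 47L, 54L)),
    stringsAsFactors = FALSE)
}

cif_tokens <- function(line) {
  # whitespace-split honouring single/double quotes
  m <- gregexpr("'[^']*'|\"[^\"]*\"|\\S+", line)[[1]]
  if (m[1L] == -1L) return(character(0))
  tok <- regmatches(line, gregexpr("'[^']*'|\"[^\"]*\"|\\S+", line))[[1]]
  gsub("^['\"]|['\"]$", "", tok)
}

parse_cif_lines <- function(lines) {
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (grepl("^\\s*loop_\\s*$", lines[i])) {
      j <- i + 1L
      tags <- character(0)
      while (j <= n && grepl("^\\s*_", lines[j])) {
        tags <- c(tags, trimws(lines[j]))
        j <- j + 1L
      }
      if (length(tags) && all(startsWith(tags, "_atom_site."))) {
        fields <- sub("^_atom_site\\.", "", tags)
        rows <- list()
        while (j <= n && !grepl("^\\s*(loop_|_|#|data_)", lines[j]) &&
               nzchar(trimws(lines[j]))) {
          rows[[length(rows) + 1L]] <- cif_tokens(lines[j])
          j <- j + 1L
        }
        return(cif_atom_frame(fields, rows))
      }
      i <- j
    } else i <- i + 1L
  }
  data.frame(chain = character(0), resnum = integer(0), icode = character(0),
             resname = character(0), atom = character(0), x = double(0),
             y = double(0), z = double(0))
}

cif_atom_frame <- function(fields, rows) {
  m <- do.call(rbind, rows)
  colnames(m) <- fields
  pick <- function(...) {
    for (f in c(...)) if (f %in% fields) return(m[, f])
    rep(NA_character_, nrow(m))
  }
  grp <- pick("group_PDB")
  keep <- is.na(grp) | grp %in% c("ATOM", "HETATM")
  mod <- pick("pdbx_PDB_model_num")
  if (!all(is.na(mod))) keep <- keep & mod == mod[which(keep)[1L]]
  alt <- pick("label_alt_id")
  keep <- keep & (is.na(alt) | alt %in% c(".", "?", "A"))
  m <- m[keep, , drop = FALSE]
  blank <- function(v) ifelse(v %in% c(".", "?") | is.na(v), "", v)
  get <- function(...) {
    for (f in c(...)) if (f %in% fields) return(m[, f])
    rep(NA_character_, nrow(m))
  }
  data.frame(
    chain = blank(get("auth_asym_id", "label_asym_id")),
    resnum = as.integer(blank(get("auth_seq_id", "label_seq_id"))),
    icode = blank(get("pdbx_PDB_ins_code")),
    resname = get("auth_comp_id", "label_comp_id"),
    atom = get("auth_atom_id", "label_atom_id"),
    x = as.numeric(get("Cartn_x")),
    y = as.numeric(get("Cartn_y")),
    z = as.numeric(get("Cartn_z")),
    stringsAsFactors = FALSE)
}

#' Write an atom table as a PDB file
#'
#' Used by the synthetic-structure generator; emits standard fixed-width
#' ATOM records.
#'
#' @param atoms An `atom_table`.
#' @param path File path.
#' @export
write_structure_pdb <- function(atoms, path) {
  name4 <- vapply(atoms$atom, function(a) {
    a <- gsub("'", "'", a)
    if (nchar(a) < 4L) sprintf(" %-3s", a) else substr(a, 1L, 4L)
  }, "")
  lines <- sprintf("ATOM  %5d %4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f  1.00  0.00",
                   seq_len(nrow(atoms)), name4, atoms$resname,
                   substr(atoms$chain, 1L, 1L), atoms$resnum,
                   ifelse(atoms$icode == "", " ", atoms$icode),
                   atoms$x, atoms$y, atoms$z)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Read / write a base-pair annotation table
#'
#' Tab-separated columns: chain_i, resnum_i, chain_j, resnum_j, class
#' (AU/GC/GU in either letter order). Such a table, typically produced by
#' external annotation software, overrides the built-in geometric detector.
#'
#' @param path File path.
#' @export
read_basepair_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("chain_i", "resnum_i", "chain_j", "resnum_j", "class")
  if (!all(need %in% names(df)))
    stop("annotation table needs columns: ", paste(need, collapse = ", "))
  df
}

#' @rdname read_basepair_table
#' @param pairs Base-pair data frame.
#' @export
write_basepair_table <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
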