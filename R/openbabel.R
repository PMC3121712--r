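# OpenBabel bridge. Structure interpretation (SMILES/SDF/InChI) is delegated to
# OpenBabel: ChemmineOB::convertFormat for in-process format conversion, and the
# obabel CLI for standard InChI with AuxInfo (the auxiliary /N: layer carries the
# canonical atom order, which ChemmineOB does not expose). All CLI calls are
# batched: one process per multi-record input.

ob_available <- function() nzchar(Sys.which("obabel"))

# Run obabel over `input` text (possibly multi-record), returning stdout lines.
ob_run <- function(input, in_format, out_format, args = character()) {
  if (!ob_available()) stop("obabel executable not found on PATH")
  fin <- tempfile(fileext = paste0(".", in_format))
  fout <- tempfile()
  on.exit(unlink(c(fin, fout)), add = TRUE)
  writeLines(input, fin)
  status <- suppressWarnings(system2(
    "obabel", c(paste0("-i", in_format), shQuote(fin),
                paste0("-o", out_format), "-O", shQuote(fout), args),
    stdout = FALSE, stderr = FALSE))
  if (!identical(status, 0L) || !file.exists(fout))
    stop("obabel conversion ", in_format, " -> ", out_format, " failed")
  readLines(fout, warn = FALSE)
}

# Standard InChI plus AuxInfo for each V2000 mol block. Returns a data.frame
# with one row per record: inchi, aux.
ob_inchi <- function(molblocks) {
  lines <- ob_run(unlist(strsplit(paste0(molblocks, collapse = "\n"), "\n")),
                  "sdf", "inchi", "-xa")
  lines <- lines[nzchar(lines)]
  inchi <- grep("^InChI=", lines, value = TRUE)
  aux <- grep("^AuxInfo=", lines, value = TRUE)
  if (length(inchi) != length(molblocks) || length(aux) != length(molblocks))
    stop("InChI generation failed for ",
         length(molblocks) - min(length(inchi), length(aux)),
         " of ", length(molblocks), " structures (not representable?)")
  data.frame(inchi = inchi, aux = aux, stringsAsFactors = FALSE)
}

# InChIKeys for a vector of InChI strings.
ob_inchikey <- function(inchis) {
  if (!length(inchis)) return(character())
  keys <- ob_run(inchis, "inchi", "inchikey")
  keys <- trimws(keys[nzchar(trimws(keys))])
  if (length(keys) != length(inchis)) stop("InChIKey generation failed")
  keys
}

inchikey_pattern <- "^[A-Z]{14}-[A-Z]{10}-[A-Z]$"

# Canonical SMILES for each V2000 mol block (batched CLI call; OpenBabel's
# kekulization notes for open-chain aromatic fragments stay on stderr).
ob_canonical_smiles <- function(molblocks) {
  if (!length(molblocks)) return(character())
  rows <- ob_run(unlist(strsplit(paste0(molblocks, collapse = "\n"), "\n")),
                 "sdf", "can")
  rows <- rows[nzchar(trimws(rows))]
  if (length(rows) != length(molblocks))
    stop("canonical SMILES generation failed (", length(rows), "/",
         length(molblocks), " records)")
  vapply(strsplit(rows, "\t"), `[`, "", 1L)
}

# SMILES -> V2000 mol blocks (one per input SMILES), via ChemmineOB.
ob_smiles_to_molblocks <- function(smiles) {
  if (!length(smiles)) return(character())
  out <- ChemmineOB::convertFormat("SMI", "SDF", paste0(smiles, "\n", collapse = ""))
  blocks <- split_sdf(out)
  if (length(blocks) != length(smiles))
    stop("SMILES interpretation failed (", length(blocks), "/", length(smiles),
         " records converted)")
  blocks
}

ob_inchi_to_molblock <- function(inchi) {
  out <- ChemmineOB::convertFormat("INCHI", "SDF", paste0(inchi, "\n"))
  blocks <- split_sdf(out)
  if (length(blocks) != 1L) stop("InChI interpretation failed: ", inchi)
  blocks[[1L]]
}

# Split concatenated SDF text into individual records (without the $$$$ line).
split_sdf <- function(text) {
  lines <- unlist(strsplit(text, "\n"))
  ends <- grep("^\\$\\$\\$\\$", lines)
  if (!length(ends)) {
    if (!any(nzchar(lines))) return(list())
    return(list(paste0(lines, collapse = "\n")))
  }
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  Map(function(s, e) paste0(lines[s:(e - 1L)], collapse = "\n"), starts, ends)
}

ob_version <- function() {
  if (!is.null(.chess_env$ob_version)) return(.chess_env$ob_version)
  out <- tryCatch(system2("obabel", "-V", stdout = TRUE, stderr = TRUE),
                  error = function(e) "Open Babel (version unknown)")
  .chess_env$ob_version <- paste(out, collapse = " ")
  .chess_env$ob_version
}
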