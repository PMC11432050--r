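## Molecule I/O, washing, structural alerts and open 2D descriptors.
## Structure handling is delegated to ChemmineR / ChemmineOB (OpenBabel).

#' Construct a MoleculeSet
#'
#' @param id character vector of unique ids.
#' @param smiles character vector of SMILES strings.
#' @param source free-text source tag, recycled.
#' @param rejects optional data.frame of rejected entries
#'   (`id`, `structure`, `reason`).
#' @return a [MoleculeSet].
#' @export
MoleculeSet <- function(id, smiles, source = "unknown", rejects = NULL) {
  if (is.null(rejects))
    rejects <- data.frame(id = character(), structure = character(),
                          reason = character())
  new("MoleculeSet", id = as.character(id), smiles = as.character(smiles),
      source = rep_len(as.character(source), length(id)), rejects = rejects)
}

## OpenBabel accepts some malformed SMILES (e.g. an unclosed branch) by
## silently repairing them, so a bracket-balance pre-check is applied before
## conversion to honour the "no silent drops" contract.
.balancedSmiles <- function(s) {
  vapply(s, function(x) {
    chars <- strsplit(x, "")[[1L]]
    open <- sum(chars == "(") - sum(chars == ")")
    sq <- sum(chars == "[") - sum(chars == "]")
    open == 0L && sq == 0L && nzchar(x)
  }, logical(1L), USE.NAMES = FALSE)
}

## Batch-canonicalize SMILES through OpenBabel; returns a character vector
## aligned with the input, NA where conversion failed. `ops` are OpenBabel
## transformation ops (e.g. "neutralize").
.canonicalSmiles <- function(smiles, ops = NULL) {
  n <- length(smiles)
  if (!n) return(character())
  tag <- sprintf("x%07d", seq_len(n))
  txt <- paste0(paste(smiles, tag, sep = "\t"), "\n", collapse = "")
  out <- tryCatch({
    if (length(ops))
      ChemmineOB::convertFormat("SMI", "CAN", txt,
                                options = data.frame(names = ops, args = ""))
    else ChemmineOB::convertFormat("SMI", "CAN", txt)
  }, error = function(e) "")
  res <- rep(NA_character_, n)
  if (nzchar(out)) {
    lines <- strsplit(out, "\n", fixed = TRUE)[[1L]]
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    for (p in parts) {
      if (length(p) >= 2L) {
        idx <- match(trimws(p[2L]), tag)
        if (!is.na(idx)) res[idx] <- p[1L]
      }
    }
  }
  res
}

#' Read molecules from a SMILES or SDF file
#'
#' SMILES files hold one molecule per line: a SMILES token optionally
#' followed by whitespace and an identifier (default `mol<n>`). Unparseable
#' entries are counted, reported via [message()] and retained in the
#' `rejects` slot rather than silently dropped.
#'
#' @param path file path.
#' @param format `"smiles"` or `"sdf"`.
#' @param source free-text source tag stored on every record.
#' @return a [MoleculeSet].
#' @export
readMolecules <- function(path, format = c("smiles", "sdf"),
                          source = "file") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "smiles") {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    if (!length(lines)) stop("no molecules in ", path)
    smi <- sub("\\s.*$", "", lines)
    id <- trimws(sub("^\\S+\\s*", "", lines))
    id[!nzchar(id)] <- sprintf("mol%d", which(!nzchar(id)))
    if (anyDuplicated(id))
      stop("duplicate molecule id: ", id[duplicated(id)][1L])
    ok <- .balancedSmiles(smi)
    can <- rep(NA_character_, length(smi))
    can[ok] <- .canonicalSmiles(smi[ok])
    good <- ok & !is.na(can)
  } else {
    sdf <- ChemmineR::read.SDFset(path)
    if (!length(sdf)) stop("no molecules in ", path)
    valid <- ChemmineR::validSDF(sdf)
    id <- ChemmineR::sdfid(sdf)
    id[!nzchar(id)] <- sprintf("mol%d", which(!nzchar(id)))
    if (anyDuplicated(id))
      stop("duplicate molecule id: ", id[duplicated(id)][1L])
    smi <- rep(NA_character_, length(sdf))
    if (any(valid))
      smi[which(valid)] <- as.character(ChemmineR::sdf2smiles(sdf[which(valid)]))
    can <- smi
    good <- valid & !is.na(smi) & nzchar(smi)
  }
  if (!any(good)) stop("no parseable molecules in ", path)
  if (any(!good))
    message(sum(!good), " unparseable entr",
            if (sum(!good) == 1L) "y" else "ies", " rejected from ", path)
  rej <- data.frame(id = id[!good], structure = smi[!good],
                    reason = rep("unparseable structure", sum(!good)))
  MoleculeSet(id[good], can[good], source = source, rejects = rej)
}

## Heavy-atom counts for a vector of SMILES fragments (H excluded).
.heavyAtoms <- function(smiles) {
  vapply(seq_along(smiles), function(i) {
    sdf <- tryCatch(suppressWarnings(
      ChemmineR::smiles2sdf(smiles[i])), error = function(e) NULL)
    if (is.null(sdf)) return(NA_integer_)
    ac <- ChemmineR::atomcount(sdf[[1L]])
    sum(ac[names(ac) != "H"])
  }, integer(1L))
}

.containsCarbon <- function(smiles) {
  grepl("C|c", gsub("Cl|Ca|Cd|Co|Cr|Cu|Cs|Ce|Sc", "", smiles))
}

#' Wash molecule structures
#'
#' Standard structure cleanup before descriptor calculation: keep the
#' largest organic fragment (salt stripping; ties broken by lexicographic
#' canonical SMILES), neutralize +1/-1 charges where chemically valid, and
#' canonicalize the SMILES. Ids are preserved; molecules that fail any step
#' are routed to the rejects slot. The operation is idempotent.
#'
#' @param mset a [MoleculeSet].
#' @return a washed [MoleculeSet].
#' @export
washMolecules <- function(mset) {
  stopifnot(is(mset, "MoleculeSet"))
  n <- length(mset@id)
  if (!n) return(mset)
  kept <- character(n)
  for (i in seq_len(n)) {
    frags <- strsplit(mset@smiles[i], ".", fixed = TRUE)[[1L]]
    frags <- frags[nzchar(frags)]
    if (!length(frags)) { kept[i] <- NA_character_; next }
    if (length(frags) == 1L) { kept[i] <- frags; next }
    ha <- .heavyAtoms(frags)
    organic <- .containsCarbon(frags)
    cand <- if (any(organic & !is.na(ha))) which(organic & !is.na(ha))
            else which(!is.na(ha))
    if (!length(cand)) { kept[i] <- NA_character_; next }
    best <- cand[ha[cand] == max(ha[cand])]
    if (length(best) > 1L) {
      can <- .canonicalSmiles(frags[best])
      best <- best[order(can, method = "radix")][1L]
    }
    kept[i] <- frags[best]
  }
  ok <- !is.na(kept)
  washed <- rep(NA_character_, n)
  washed[ok] <- .canonicalSmiles(kept[ok], ops = "neutralize")
  good <- ok & !is.na(washed)
  rej <- mset@rejects
  if (any(!good)) {
    message(sum(!good), " molecule(s) rejected during wash")
    rej <- rbind(rej, data.frame(id = mset@id[!good],
                                 structure = mset@smiles[!good],
                                 reason = rep("wash failure", sum(!good))))
  }
  MoleculeSet(mset@id[good], washed[good], source = mset@source[good],
              rejects = rej)
}

## Descriptor set "ob2d": open 2D physicochemical descriptors computed with
## OpenBabel/ChemmineR, pinned here and recorded in table provenance.
.OB2D <- c("MW", "logP", "TPSA", "HBA", "HBD", "MR", "nF",
           "rings", "aromaticRings", "heavyAtoms")

#' Compute 2D molecular descriptors
#'
#' Computes the pinned open descriptor set `"ob2d"`: molecular weight, logP
#' estimate, topological polar surface area, H-bond acceptors and donors,
#' molar refractivity, fluorine count, ring and aromatic ring counts, and
#' heavy-atom count. Molecules for which any descriptor is non-finite are
#' routed to the rejects slot of the returned table's attributes.
#'
#' @param mset a washed [MoleculeSet].
#' @param descriptorSet descriptor set name; only `"ob2d"` is built in.
#'   Arbitrary precomputed tables can be supplied to downstream steps via
#'   [readDescriptorCsv()] instead.
#' @return a [DescriptorTable]; rejected molecules (if any) are reported via
#'   `message()` and attached as attribute `"rejects"`.
#' @export
computeDescriptors <- function(mset, descriptorSet = "ob2d") {
  stopifnot(is(mset, "MoleculeSet"))
  if (!identical(descriptorSet, "ob2d"))
    stop("unknown descriptor set: ", descriptorSet)
  if (!length(mset@id)) stop("no molecules to compute descriptors for")
  sdf <- ChemmineR::smiles2sdf(setNames(mset@smiles, mset@id))
  props <- ChemmineR::propOB(sdf)
  ring <- ChemmineR::rings(sdf, type = "count", arom = TRUE)
  heavy <- vapply(seq_along(sdf), function(i) {
    ac <- ChemmineR::atomcount(sdf[[i]])
    sum(ac[names(ac) != "H"])
  }, numeric(1L))
  m <- cbind(MW = props$MW, logP = props$logP, TPSA = props$TPSA,
             HBA = props$HBA1, HBD = props$HBD, MR = props$MR,
             nF = props$nF, rings = ring[, "RINGS"],
             aromaticRings = ring[, "AROMATIC"], heavyAtoms = heavy)
  rownames(m) <- mset@id
  bad <- apply(m, 1L, function(r) any(!is.finite(r)))
  if (any(bad))
    message(sum(bad), " molecule(s) rejected: non-finite descriptor values")
  tab <- new("DescriptorTable", values = m[!bad, , drop = FALSE],
             provenance = "ob2d")
  attr(tab, "rejects") <- data.frame(
    id = mset@id[bad], structure = mset@smiles[bad],
    reason = rep("non-finite descriptor", sum(bad)))
  tab
}

#' Default structural alert set
#'
#' A small documented set of SMARTS patterns for reactive groups (acyl
#' halide, aldehyde, epoxide, Michael acceptor, isocyanate) and mutagenicity
#' flags (nitro-aromatic, aromatic azo). Replace or extend freely; an empty
#' alert set disables alert filtering.
#'
#' @return data.frame with columns `name` and `smarts`.
#' @export
defaultAlerts <- function() {
  data.frame(
    name = c("acyl_halide", "aldehyde", "epoxide", "michael_acceptor",
             "isocyanate", "nitro_aromatic", "aromatic_azo"),
    smarts = c("[CX3](=O)[F,Cl,Br,I]",
               "[CX3H1](=O)[#6]",
               "C1OC1",
               "[CX3]=[CX3][CX3]=[OX1]",
               "[NX2]=C=O",
               "[a][$([NX3](=O)=O),$([NX3+](=O)[O-])]",
               "[a][NX2]=[NX2][a]"))
}

#' Partition molecules by structural alerts
#'
#' A molecule is flagged iff at least one SMARTS pattern matches; the
#' partition is exhaustive and disjoint. An empty alert set flags nothing.
#'
#' @param mset a [MoleculeSet].
#' @param alerts data.frame with columns `name`, `smarts`
#'   (default [defaultAlerts()]).
#' @return list with elements `clean` and `flagged` ([MoleculeSet]s) and
#'   `matches` (data.frame of `id`, `alert`).
#' @export
flagAlerts <- function(mset, alerts = defaultAlerts()) {
  stopifnot(is(mset, "MoleculeSet"))
  stopifnot(all(c("name", "smarts") %in% names(alerts)))
  n <- length(mset@id)
  hit <- rep(FALSE, n)
  matches <- data.frame(id = character(), alert = character())
  if (n && nrow(alerts)) {
    sdf <- ChemmineR::smiles2sdf(setNames(mset@smiles, mset@id))
    for (j in seq_len(nrow(alerts))) {
      cnt <- ChemmineR::smartsSearchOB(sdf, alerts$smarts[j],
                                       uniqueMatches = FALSE)
      m <- cnt > 0
      if (any(m))
        matches <- rbind(matches,
                         data.frame(id = mset@id[m], alert = alerts$name[j]))
      hit <- hit | m
    }
  }
  sub <- function(keep) MoleculeSet(mset@id[keep], mset@smiles[keep],
                                    source = mset@source[keep])
  list(clean = sub(!hit), flagged = sub(hit), matches = matches)
}

#' Create a DescriptorTable from a matrix or data.frame
#'
#' @param values numeric matrix or data.frame (rows = molecules).
#' @param ids optional molecule ids (default: rownames).
#' @param provenance free-text provenance tag.
#' @return a [DescriptorTable].
#' @export
DescriptorTable <- function(values, ids = rownames(values),
                            provenance = NA_character_) {
  m <- as.matrix(values)
  storage.mode(m) <- "double"
  rownames(m) <- ids
  new("DescriptorTable", values = m, provenance = provenance)
}

#' Read / write a descriptor CSV
#'
#' The CSV has a header row with the id column first, then one column per
#' descriptor. `writeDescriptorCsv()` serializes doubles at full precision
#' (C "%.17g") so a write/read round trip reproduces values bit-exactly.
#' Non-numeric cells and duplicate ids are errors naming the offending
#' row/column.
#'
#' @param path CSV file path.
#' @return [readDescriptorCsv()] returns a [DescriptorTable].
#' @export
readDescriptorCsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2L) stop("descriptor CSV needs an id column plus descriptors")
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate id: ", ids[duplicated(ids)][1L])
  desc <- names(df)[-1L]
  if (anyDuplicated(desc))
    stop("duplicate descriptor name: ", desc[duplicated(desc)][1L])
  m <- matrix(NA_real_, nrow(df), length(desc),
              dimnames = list(ids, desc))
  for (j in seq_along(desc)) {
    x <- suppressWarnings(as.numeric(df[[j + 1L]]))
    bad <- which(!is.finite(x))
    if (length(bad))
      stop(sprintf("non-numeric or missing value at (row %d, column '%s')",
                   bad[1L], desc[j]))
    m[, j] <- x
  }
  new("DescriptorTable", values = m,
      provenance = paste0("csv:", basename(path)))
}

#' @rdname readDescriptorCsv
#' @param table a [DescriptorTable] to write.
#' @export
writeDescriptorCsv <- function(table, path) {
  stopifnot(is(table, "DescriptorTable"))
  v <- table@values
  lines <- c(paste(c("id", colnames(v)), collapse = ","),
             vapply(seq_len(nrow(v)), function(i) {
               paste(c(rownames(v)[i], sprintf("%.17g", v[i, ])),
                     collapse = ",")
             }, character(1L)))
  writeLines(lines, path)
  invisible(path)
}
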