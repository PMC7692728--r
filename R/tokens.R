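# Domain-organization grammar: catalytic-domain tokens and the compact
# architecture notation ("/" between domains, "-" between modules).

# Domain kinds. KS3 is the free-standing chalcone-synthase-like type-III KS;
# KS with qualifier "first" is the loading-module KS (printed KS_1).
.DOMAIN_KINDS <- c("KS", "KS3", "AT", "ACP", "KR", "DH", "ER", "MT",
                   "A", "T", "C", "E", "TE", "TD", "CoL", "FkbH")

.AT_QUALIFIERS <- c("m", "p", "e")
.C_SUBTYPES    <- c("LCL", "DCL", "Du", "M", "S", "Cy")
.KS_QUALIFIERS <- c("first")

# Monomer vocabulary for A (and CoL) substrate tags. "horn" only ever arrives
# through a specificity-code call, "ahba" through a CoL starter.
.MONOMERS <- c("asn", "ser", "gly", "orn", "haorn", "horn", "val", "thr",
               "tyr", "asp", "phe", "leu", "cys", "pro", "gln", "dhb",
               "aad", "ala", "ahba", "asx")

# Display names used in product chains.
.MONOMER_DISPLAY <- c(asn = "Asn", ser = "Ser", gly = "Gly", orn = "Orn",
                      haorn = "HaOrn", horn = "hOrn", val = "Val",
                      thr = "Thr", tyr = "Tyr", asp = "Asp", phe = "Phe",
                      leu = "Leu", cys = "Cys", pro = "Pro", gln = "Gln",
                      dhb = "DHB", aad = "Aad", ala = "Ala", ahba = "AHBA",
                      asx = "Asx")

#' Construct a domain token
#'
#' A single catalytic domain with its kind, an optional qualifier (substrate
#' of an A domain or CoA-ligase, acyl unit of an AT domain, subtype of a C
#' domain, "first" for a loading-module KS) and a confidence flag. Tentative
#' confidence encodes substrate calls supported by a single predictor only
#' (set in printed tables in italics); it is legal only on A-domain
#' substrate qualifiers.
#'
#' @param kind domain class, one of `KS`, `KS3`, `AT`, `ACP`, `KR`, `DH`,
#'   `ER`, `MT`, `A`, `T`, `C`, `E`, `TE`, `TD`, `CoL`, `FkbH`.
#' @param qualifier optional tag; namespace depends on `kind`.
#' @param tentative logical; single-predictor substrate call.
#' @return a one-row data frame with columns `kind`, `qualifier`,
#'   `tentative`.
#' @export
domain_token <- function(kind, qualifier = NA_character_, tentative = FALSE) {
  if (!kind %in% .DOMAIN_KINDS)
    stop("unknown domain kind: ", kind)
  if (!is.na(qualifier)) {
    ok <- switch(kind,
                 AT  = qualifier %in% .AT_QUALIFIERS,
                 A   = qualifier %in% .MONOMERS,
                 CoL = qualifier %in% .MONOMERS,
                 C   = qualifier %in% .C_SUBTYPES,
                 KS  = qualifier %in% .KS_QUALIFIERS,
                 FALSE)
    if (!ok)
      stop("qualifier '", qualifier, "' is not legal for domain kind ", kind)
  }
  if (tentative && !(kind == "A" && !is.na(qualifier)))
    stop("tentative confidence is only allowed on A-domain substrate qualifiers")
  data.frame(kind = kind, qualifier = qualifier, tentative = tentative,
             stringsAsFactors = FALSE)
}

.empty_tokens <- function() {
  data.frame(kind = character(), qualifier = character(),
             tentative = logical(), stringsAsFactors = FALSE)
}

# Normalize the typographic dialect of printed tables to plain ASCII before
# tokenization: en dashes, superscript C-subtype prefixes, italics markers,
# trailing underscores.
.normalize_architecture_text <- function(text) {
  s <- text
  s <- gsub("–|—", "-", s)              # en/em dash -> hyphen
  s <- gsub("\\^L\\^C_L_?", "LCL", s)
  s <- gsub("\\^D\\^C_L_?", "DCL", s)
  s <- gsub("\\*_([a-z]+)_\\*", "_\\1?", s)        # italic substrate -> tentative
  s <- gsub("KS \\(type-III PKS\\)", "KS3", s)
  gsub("[[:space:]]+", " ", trimws(s))
}

# Parse one token string (already split); returns one-row token data frame or
# NULL on failure.
.parse_one_token <- function(tok) {
  t <- sub("_$", "", tok)
  # fixed-form kinds
  fixed <- c(ACP = "ACP", KR = "KR", DH = "DH", ER = "ER", MT = "MT",
             T = "T", E = "E", TE = "TE", TD = "TD", FkbH = "FkbH",
             KS = "KS", KS3 = "KS3", AT = "AT", A = "A", CoL = "CoL",
             C = "C")
  if (t %in% names(fixed))
    return(domain_token(unname(fixed[t])))
  if (t %in% c("KS_1", "KS1"))
    return(domain_token("KS", "first"))
  # C subtypes
  csub <- c(LCL = "LCL", C_L = "LCL", DCL = "DCL", C_D = "DCL",
            C_Du = "Du", C_M = "M", C_S = "S", C_Cy = "Cy")
  if (t %in% names(csub))
    return(domain_token("C", unname(csub[t])))
  m <- regmatches(t, regexec("^AT_([mpe])$", t))[[1]]
  if (length(m) == 2)
    return(domain_token("AT", m[2]))
  m <- regmatches(t, regexec("^A_([a-z]+)(\\?)?$", t))[[1]]
  if (length(m) >= 2 && m[2] %in% .MONOMERS)
    return(domain_token("A", m[2], tentative = nzchar(m[3])))
  m <- regmatches(t, regexec("^CoL_([A-Za-z]+)$", t))[[1]]
  if (length(m) == 2 && tolower(m[2]) %in% .MONOMERS)
    return(domain_token("CoL", tolower(m[2])))
  NULL
}

#' Parse a domain-organization string
#'
#' Reads the compact assembly-line notation used in cluster tables: "/" (or
#' whitespace) separates domains, "-" (hyphen or en dash) separates modules.
#' Superscript C-domain subtype prefixes (`^L^C_L`, `^D^C_L`) and the plain
#' forms `C_L`/`C_D`, subtype suffixes (`C_Du`, `C_M`, `C_S`, `C_Cy`),
#' substrate tags (`AT_m`, `A_ser`), tentative substrate markers (`A_ser?`,
#' or italics markup `A*_ser_*`), `KS_1` and `KS3` / `KS (type-III PKS)` are
#' all recognised. Stray separators (doubled or leading/trailing) are
#' dropped; unknown tokens are an error, never silently skipped.
#'
#' @param text a domain-organization string.
#' @param locus_tag,strand,length_aa optional ORF annotation carried on the
#'   result; `strand` is `"forward"` or `"complement"`.
#' @return an object of class `orf_architecture`: list with `locus_tag`,
#'   `strand`, `length_aa`, `tokens` (data frame of domain tokens in order)
#'   and `boundaries` (integer positions i such that a module separator was
#'   printed after token i).
#' @examples
#' parse_architecture("KS/AT_m_/KR/DH")
#' parse_architecture("A_haorn/MT/T-DCL/A/T")
#' @export
parse_architecture <- function(text, locus_tag = NA_character_,
                               strand = "forward",
                               length_aa = NA_integer_) {
  stopifnot(is.character(text), length(text) == 1)
  stopifnot(strand %in% c("forward", "complement"))
  s <- .normalize_architecture_text(text)
  if (!nzchar(s)) stop("empty domain-organization string")
  # Split into module chunks on hyphens, then tokens on "/" or space.
  chunks <- strsplit(s, "-", fixed = TRUE)[[1]]
  toks <- .empty_tokens()
  boundaries <- integer()
  pos <- 0L
  for (ci in seq_along(chunks)) {
    raw <- strsplit(chunks[ci], "[/ ]+")[[1]]
    raw <- raw[nzchar(raw)]
    for (tk in raw) {
      parsed <- .parse_one_token(tk)
      pos <- pos + 1L
      if (is.null(parsed))
        stop("unparseable domain token '", tk, "' at position ", pos,
             " in \"", text, "\"")
      toks <- rbind(toks, parsed)
    }
    if (ci < length(chunks) && nrow(toks) > 0)
      boundaries <- c(boundaries, nrow(toks))
  }
  if (nrow(toks) == 0) stop("no domain tokens in \"", text, "\"")
  # drop non-interior boundaries left by stray separators
  boundaries <- unique(boundaries[boundaries >= 1 & boundaries < nrow(toks)])
  structure(list(locus_tag = locus_tag, strand = strand,
                 length_aa = length_aa, tokens = toks,
                 boundaries = as.integer(boundaries)),
            class = "orf_architecture")
}

.serialize_token <- function(kind, qualifier, tentative) {
  if (kind == "C") {
    if (is.na(qualifier)) return("C")
    return(switch(qualifier, LCL = "LCL", DCL = "DCL",
                  paste0("C_", qualifier)))
  }
  if (kind == "KS" && !is.na(qualifier) && qualifier == "first")
    return("KS1")
  if (is.na(qualifier)) return(kind)
  paste0(kind, "_", qualifier, if (isTRUE(tentative)) "?" else "")
}

#' Serialize an ORF architecture to its canonical ASCII form
#'
#' Inverse of [parse_architecture()]: "/" between domains, "-" between
#' modules, `A_ser?` for tentative substrate calls. `parse(serialize(x))`
#' reproduces `x`'s tokens and boundaries exactly.
#'
#' @param arch an `orf_architecture`.
#' @return a character scalar.
#' @export
serialize_architecture <- function(arch) {
  stopifnot(inherits(arch, "orf_architecture"))
  tk <- arch$tokens
  words <- mapply(.serialize_token, tk$kind, tk$qualifier, tk$tentative,
                  USE.NAMES = FALSE)
  n <- length(words)
  sep <- rep("/", max(n - 1, 0))
  if (length(arch$boundaries)) sep[arch$boundaries] <- "-"
  out <- words[1]
  if (n > 1) out <- paste0(out, paste0(sep, words[-1], collapse = ""))
  out
}

#' @export
print.orf_architecture <- function(x, ...) {
  tag <- if (is.na(x$locus_tag)) "<orf>" else x$locus_tag
  star <- if (x$strand == "complement") " (complement)" else ""
  cat(tag, star, ": ", serialize_architecture(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.orf_architecture <- function(x, ...) serialize_architecture(x)

# value equality used by round-trip tests
.arch_equal <- function(a, b) {
  identical(a$tokens$kind, b$tokens$kind) &&
    identical(is.na(a$tokens$qualifier), is.na(b$tokens$qualifier)) &&
    all(a$tokens$qualifier == b$tokens$qualifier, na.rm = TRUE) &&
    identical(a$tokens$tentative, b$tokens$tentative) &&
    identical(a$boundaries, b$boundaries)
}
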