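# Shared helpers: IUPAC alphabet, small numeric utilities.

IUPAC_RNA <- list(
    A = "A", C = "C", G = "G", U = "U",
    R = c("A", "G"), Y = c("C", "U"), W = c("A", "U"), S = c("C", "G"),
    K = c("G", "U"), M = c("A", "C"),
    B = c("C", "G", "U"), D = c("A", "G", "U"), H = c("A", "C", "U"),
    V = c("A", "C", "G"), N = c("A", "C", "G", "U")
)

# Normalize a nucleotide string to RNA-alphabet character vector (T -> U).
# "X" is the mask placeholder written by maskFBE(); it matches nothing.
.toRnaChars <- function(seq) {
    s <- strsplit(chartr("tT", "uU", toupper(seq)), "", fixed = TRUE)[[1]]
    bad <- !(s %in% c(names(IUPAC_RNA), "X"))
    if (any(bad))
        stop("invalid nucleotide characters: ",
             paste(unique(s[bad]), collapse = ", "))
    s
}

.clamp01 <- function(p) pmin(1, pmax(p, 1e-300))

# Random barcode strings.
.randomBarcodes <- function(n, len) {
    if (n == 0L) return(character())
    m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE),
                nrow = n)
    apply(m, 1, paste0, collapse = "")
}

.checkCount <- function(x, name) {
    if (length(x) != 1L || is.na(x) || x < 0)
        stop(name, " must be a single nonnegative number")
    invisible(x)
}

# Overflow-safe derived seed (stays below 2^31 for any integer master seed).
.deriveSeed <- function(seed, k) {
    as.integer((as.numeric(seed) * 131 + as.numeric(k)) %% 2147483629)
}
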