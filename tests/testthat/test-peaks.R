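# Candidate discovery (20%-border rule), 5'-end binning, background tail
# probabilities, BH adjustment, and the six-method caller.

rleCov <- function(v) S4Vectors::Rle(as.integer(v))

test_that("peak borders fall at 20% of the peak height", {
    v <- c(0, 1, 5, 10, 5, 1, 0)
    p <- findCandidatePeaks(rleCov(v), config = peakCallConfig(minHeight = 5))
    expect_length(p, 1)
    # threshold 2: the three positions with coverage >= 2 form the span
    expect_equal(BiocGenerics::start(p), 3L)
    expect_equal(BiocGenerics::end(p), 5L)
    expect_equal(p$height, 10L)
    expect_equal(p$maxPos, 4L)
    expect_length(findCandidatePeaks(rleCov(rep(0, 50))), 0)
})

test_that("overlapping extents merge into one peak with the taller height", {
    v <- rep(0, 40)
    v[10:18] <- c(3, 6, 10, 6, 3, 5, 8, 5, 3)   # 20% extents overlap
    p <- findCandidatePeaks(rleCov(v), config = peakCallConfig(minHeight = 5))
    expect_length(p, 1)
    expect_equal(p$height, 10L)
    expect_equal(p$maxPos, 12L)
})

test_that("candidate discovery matches the brute-force oracle", {
    set.seed(21)
    cfg <- peakCallConfig(minHeight = 5)
    for (rep in 1:100) {
        v <- pmax(0L, as.integer(rpois(120, 1.2) +
            ifelse(runif(120) < 0.05, rpois(120, 12), 0)))
        got <- findCandidatePeaks(rleCov(v), config = cfg)
        want <- bruteCandidates(v, 5, 0.2)
        if (is.null(want)) {
            expect_length(got, 0)
        } else {
            expect_equal(cbind(start = BiocGenerics::start(got),
                               end = BiocGenerics::end(got)), want)
            for (k in seq_along(got))
                expect_equal(got$height[k],
                             max(v[BiocGenerics::start(got)[k]:
                                   BiocGenerics::end(got)[k]]))
        }
    }
})

test_that("5'-end binning tiles 50-nt bins with a kept partial bin", {
    region <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100))
    reads <- makeReads("chr1", c(1L, 50L, 51L), c(35L, 84L, 85L))
    expect_equal(binReads(reads, region), c(2L, 1L))
    expect_equal(binReads(makeReads("chr1", integer(), integer()), region),
                 c(0L, 0L))
    expect_error(binReads(reads,
        GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 30))), "shorter")
    # random fixture equals a histogram oracle (region 1..230, 5 bins)
    set.seed(31)
    for (rep in 1:100) {
        s <- sample(1:230, 40, replace = TRUE)
        rr <- makeReads("chr1", s, s + 20L)
        reg <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 230))
        want <- as.integer(table(factor((s - 1) %/% 50 + 1, levels = 1:5)))
        expect_equal(binReads(rr, reg), want)
    }
})

test_that("background tail probabilities match closed forms and oracles", {
    expect_equal(backgroundPvalue(0, c(5, 5, 5), "gaussian"), 1)
    expect_equal(backgroundPvalue(0, c(5, 5, 5), "poisson"), 1)
    expect_equal(backgroundPvalue(0, c(5, 5, 5), "negbinom"), 1)
    expect_error(backgroundPvalue(-1, c(1, 2)), "nonnegative")
    expect_error(backgroundPvalue(3, integer()), "non-empty")
    # Poisson: series-summation oracle, lambda = 1, x = 10
    # (forward sum of the tail avoids cancellation; ~1.11e-7)
    oracle <- sum(exp(-1) / factorial(10:40))
    expect_equal(backgroundPvalue(10, rep(1L, 20), "poisson"), oracle,
                 tolerance = 1e-12)
    # Gaussian symmetry: all bins equal mu, x = mu -> 0.5
    expect_equal(backgroundPvalue(7, rep(7L, 10), "gaussian"), 0.5)
    # Gaussian upper tail equals the complementary-error-function form:
    # P(X >= x) = erfc((x - mu) / (sigma sqrt 2)) / 2, with
    # erfc(z) = 2 pnorm(-z sqrt 2) (cancellation-free form)
    erfc <- function(z) 2 * stats::pnorm(-z * sqrt(2))
    set.seed(77)
    for (rep in 1:100) {
        bins <- rpois(sample(5:30, 1), runif(1, 0.5, 20))
        x <- sample(0:40, 1)
        m <- mean(bins); s <- max(stats::sd(bins), 1)
        got <- backgroundPvalue(x, bins, "gaussian")
        want <- if (x == 0) 1
                else max(min(0.5 * erfc((x - m) / (s * sqrt(2))), 1), 1e-300)
        expect_equal(got, want, tolerance = 1e-12)
    }
    # monotonicity: increasing x never increases p
    for (model in c("gaussian", "poisson", "negbinom")) {
        bins <- rpois(15, 3)
        ps <- vapply(0:25, backgroundPvalue, numeric(1),
                     bgBins = bins, model = model)
        expect_true(all(diff(ps) <= 1e-15))
    }
})

test_that("negative-binomial fit falls back to Poisson when var <= mean", {
    underdispersed <- rep(3L, 12)
    expect_equal(backgroundPvalue(9, underdispersed, "negbinom"),
                 backgroundPvalue(9, underdispersed, "poisson"))
    overdispersed <- c(0L, 0L, 1L, 0L, 9L, 14L, 0L, 1L)
    m <- mean(overdispersed); v <- var(overdispersed)
    size <- m^2 / (v - m)
    expect_equal(backgroundPvalue(20, overdispersed, "negbinom"),
                 pnbinom(19, size = size, mu = m, lower.tail = FALSE))
})

test_that("BH adjustment equals the brute-force step-up oracle", {
    bruteBH <- function(p, q) {
        # largest k with p_(k) <= k q / n; reject the k smallest
        n <- length(p)
        o <- order(p)
        ok <- which(p[o] <= seq_len(n) * q / n)
        rej <- logical(n)
        if (length(ok)) rej[o[seq_len(max(ok))]] <- TRUE
        rej
    }
    expect_equal(sum(bhAdjust(c(0.001, 0.02, 0.5)) <= 0.01), 1L)
    set.seed(13)
    for (rep in 1:100) {
        n <- sample(1:1000, 1)
        p <- runif(n)^sample(1:3, 1)
        q <- sample(c(0.01, 0.05, 0.1), 1)
        expect_identical(bhAdjust(p) <= q, bruteBH(p, q))
        expect_equal(bhAdjust(p), p.adjust(p, "BH"))
    }
})

test_that("the six-method caller applies Bonferroni and the FDR cutoff", {
    # one isolated tall pile, empty background anywhere
    s <- rep(3000L, 30)
    reads <- makeReads("chr1", s, s + 34L, seqlen = 10000L)
    cov <- readCoverage(reads, "chr1", "+")
    cands <- findCandidatePeaks(cov, "chr1", "+")
    expect_length(cands, 1)
    empty <- makeReads("chr1", integer(), integer(), seqlen = 10000L)
    calls <- callPeaks(cands, reads, controlReads = empty, method = 4L)
    expect_true(calls$significant)
    expect_equal(calls$pBonferroni,
                 pmin(1, calls$pRaw * calls$nBins))
    expect_equal(calls$nBins, 10L)
    # method/region mapping and the self background
    # the pile sits outside the toy annotation: whole-gene method 5 falls
    # back to the local region (warning checked elsewhere)
    calls5 <- suppressWarnings(callPeaks(cands, reads, method = 5L,
                                         tm = smallSim()@transcripts))
    expect_equal(calls5$method, 5L)
    expect_error(callPeaks(cands, reads, method = 7L), "1..6")
    expect_error(callPeaks(cands, reads, method = 1L), "rnaseq")
})

test_that("whole-gene methods fall back to local outside transcripts", {
    sim <- smallSim()
    reads <- makeReads(names(genomeSeq(sim))[1], rep(30L, 25), rep(64L, 25),
                       seqlen = BiocGenerics::width(genomeSeq(sim))[1])
    cov <- readCoverage(reads, names(genomeSeq(sim))[1], "+")
    cands <- findCandidatePeaks(cov, names(genomeSeq(sim))[1], "+")
    expect_warning(
        calls <- callPeaks(cands, reads, controlReads = reads, method = 3L,
                           tm = sim@transcripts),
        "outside all transcripts")
    expect_length(calls, length(cands))
})
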