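## Shared fixtures and independent oracles. Oracles are deliberately naive
## (enumeration, closed forms) and never call the code paths they check.

## Reference ROI-mean parameter sets for the two grade groups; fractions
## renormalized to unit sum (proportionally, or holding one fixed).
lowGradeParams <- function() {
    fr4 <- renormalizeFractions(c(fr = 0.060, fh = 0.413, fui = 0.275,
                                  ff = 0.219))
    madParameters(Dr = 0.039, Dh = 1.360, Df = 15.012,
                  fr = fr4["fr"], fh = fr4["fh"], fui = fr4["fui"],
                  ff = fr4["ff"], alphaH = 0.872)
}

highGradeParamsHeldFr <- function() {
    fr4 <- renormalizeFractions(c(fr = 0.080, fh = 0.442, fui = 0.274,
                                  ff = 0.196), hold = "fr")
    madParameters(Dr = 0.045, Dh = 1.254, Df = 14.335,
                  fr = fr4["fr"], fh = fr4["fh"], fui = fr4["fui"],
                  ff = fr4["ff"], alphaH = 0.896)
}

## A random parameter set in the identifiable interior of the physical
## ranges (compartments well separated; degenerate corners such as
## Dh -> 3 with alphaH -> 1 collapse onto the unimpeded compartment and
## are excluded by construction).
randomIdentifiableParams <- function() {
    fr4 <- c(fr = runif(1, 0.03, 0.12), fh = runif(1, 0.30, 0.50),
             fui = runif(1, 0.15, 0.35), ff = runif(1, 0.10, 0.30))
    fr4 <- fr4 / sum(fr4)
    madParameters(Dr = runif(1, 0, 0.12), Dh = runif(1, 0.7, 2.2),
                  Df = runif(1, 8, 40), fr = fr4["fr"], fh = fr4["fh"],
                  fui = fr4["fui"], ff = fr4["ff"],
                  alphaH = runif(1, 0.6, 1.3))
}

## Closed-form OLS slope/intercept of log(signal) on b.
olsLogSlopeOracle <- function(b, y) {
    ly <- log(y)
    sl <- sum((b - mean(b)) * (ly - mean(ly))) / sum((b - mean(b))^2)
    c(slope = sl, intercept = mean(ly) - sl * mean(b))
}

## Pairwise-concordance AUC (ties count 1/2), oriented so it is >= 0.5.
concordanceAUCOracle <- function(scores, labels) {
    pos <- scores[labels == 1]
    neg <- scores[labels == 0]
    conc <- 0
    for (p in pos) for (n in neg)
        conc <- conc + (p > n) + 0.5 * (p == n)
    a <- conc / (length(pos) * length(neg))
    max(a, 1 - a)
}

## Exact two-sided Mann-Whitney p-value by enumerating every assignment of
## the pooled sample into the two groups (no ties assumed).
mwExactPOracle <- function(x, y) {
    pooled <- c(x, y)
    n1 <- length(x)
    m <- n1 * length(y) / 2
    uOf <- function(a, b) sum(outer(a, b, ">"))
    uObs <- uOf(x, y)
    sets <- utils::combn(length(pooled), n1)
    uPerm <- apply(sets, 2, function(ix)
        uOf(pooled[ix], pooled[-ix]))
    mean(abs(uPerm - m) >= abs(uObs - m) - 1e-9)
}

## One-sample KS statistic against N(mean(x), sd(x)) by direct ECDF scan.
ksStatOracle <- function(x) {
    n <- length(x)
    Fx <- pnorm(sort(x), mean(x), sd(x))
    max(pmax(seq_len(n) / n - Fx, Fx - (seq_len(n) - 1) / n))
}

## The published clinical-characteristics counts as per-subject metadata:
## 54 subjects, 30 low-grade (1 ISUP grade 1, 29 grade 2; 18 men; T stage
## 26/0/3/1) and 24 high-grade (21 grade 3, 3 grade 4; 20 men; T stage
## 8/3/11/2). Ages are fillers within the reported ranges.
table1Metadata <- function() {
    lowGrade <- c(rep("1", 1), rep("2", 29))
    highGrade <- c(rep("3", 21), rep("4", 3))
    lowSex <- c(rep("male", 18), rep("female", 12))
    highSex <- c(rep("male", 20), rep("female", 4))
    lowT <- c(rep("T1", 26), rep("T3", 3), rep("T4", 1))
    highT <- c(rep("T1", 8), rep("T2", 3), rep("T3", 11), rep("T4", 2))
    data.frame(
        subject = sprintf("P%02d", 1:54),
        grade = c(rep("low", 30), rep("high", 24)),
        age = c(38, rep(61, 28), 76, 42, rep(62, 22), 74),
        sex = c(lowSex, highSex),
        whoIsup = c(lowGrade, highGrade),
        tStage = c(lowT, highT),
        stringsAsFactors = FALSE)
}

## Small noiseless single-tissue phantom with zero-variance truth, fitted;
## memoised because several tests reuse it.
.uniformPhantomCache <- new.env()
uniformFittedPhantom <- function() {
    if (!is.null(.uniformPhantomCache$value))
        return(.uniformPhantomCache$value)
    dist0 <- gradeDistribution("low", .zeroSdMeans(), .zeroSds())
    shape <- c(3, 3, 1)
    les <- list(low = array(TRUE, dim = shape))
    ph <- makePhantom(shape, les, dists = list(low = dist0),
                      noise = noiseConfig(0), seed = 1L)
    maps <- fitVolume(ph$dwi, ph$scheme, array(TRUE, dim = shape))
    .uniformPhantomCache$value <- list(phantom = ph, maps = maps)
    .uniformPhantomCache$value
}

.zeroSdMeans <- function() {
    pv <- paramVector(lowGradeParams())
    c(pv[c("Dr", "Dh", "Df", "fr", "fh", "fui", "ff", "alphaH")],
      ADC = 0.924)
}
.zeroSds <- function() {
    z <- rep(0, 9)
    names(z) <- c("Dr", "Dh", "Df", "fr", "fh", "fui", "ff", "alphaH",
                  "ADC")
    z
}
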