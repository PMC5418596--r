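# Independent brute-force oracles used to check the package's
# implementations. They deliberately share no code with R/.

# Local least-squares polynomial fit at every index, truncated window at
# the ends; degree reduced if the window is smaller than degree + 1.
oracleSgSmooth <- function(values, window = 11L, degree = 2L, clamp = TRUE) {
  n <- length(values)
  h <- (window - 1L) %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    idx <- max(1L, i - h):min(n, i + h)
    d <- min(degree, length(idx) - 1L)
    df <- data.frame(x = idx - i, y = values[idx])
    fit <- stats::lm(y ~ poly(x, degree = d, raw = TRUE), data = df)
    if (d == 0L) fit <- stats::lm(y ~ 1, data = df)
    out[i] <- unname(stats::predict(fit, newdata = data.frame(x = 0)))
  }
  if (clamp) out <- pmax(out, 0)
  out
}

# Two-sided Fisher p by explicit hypergeometric enumeration via lchoose.
oracleFisherEnum <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; s1 <- a + c
  if (r1 + r2 == 0) return(1)
  ks <- max(0, s1 - r2):min(r1, s1)
  logp <- lchoose(r1, ks) + lchoose(r2, s1 - ks) - lchoose(r1 + r2, s1)
  probs <- exp(logp)
  pObs <- probs[ks == a]
  min(1, sum(probs[probs <= pObs * (1 + 1e-7)]))
}

# Step-up BH definition applied literally.
oracleBH <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  sorted <- p[o]
  for (i in seq_len(m))
    q[i] <- min(1, min(m * sorted[i:m] / (i:m)))
  out <- numeric(m)
  out[o] <- q
  out
}

# Region construction by extension: starting from each unassigned DMC,
# greedily extend rightwards while each consecutive same-type link obeys
# the gap ceiling and has no opposite-type DMC strictly between.
oracleMerge <- function(pos, type, gap) {
  n <- length(pos)
  assigned <- rep(NA_integer_, n)
  rid <- 0L
  for (i in seq_len(n)) {
    if (!is.na(assigned[i])) next
    rid <- rid + 1L
    assigned[i] <- rid
    last <- i
    for (j in seq_len(n)[-seq_len(i)]) {
      if (type[j] != type[i]) next
      okGap <- (pos[j] - pos[last]) <= gap
      blocked <- any(type != type[i] & pos > pos[last] & pos < pos[j])
      if (okGap && !blocked) {
        assigned[j] <- rid
        last <- j
      } else break
    }
  }
  regions <- lapply(split(seq_len(n), assigned), function(ix)
    list(start = min(pos[ix]), end = max(pos[ix]), type = type[ix[1]],
         n = length(ix)))
  regions[order(vapply(regions, `[[`, numeric(1), "start"))]
}

# Per-base interval overlap.
oracleOverlaps <- function(s1, e1, s2, e2) {
  length(intersect(seq(s1, e1), seq(s2, e2))) >= 1
}

# Metaprofile bin means computed position by position.
oracleMetaprofile <- function(cyt, features, context, flank, bin, anchor,
                              weighted = TRUE) {
  nBins <- 2L * flank %/% bin
  accM <- accT <- accR <- accN <- numeric(nBins)
  cyt <- cyt[cyt$context == context, ]
  for (f in seq_along(features)) {
    st <- GenomicRanges::start(features)[f]
    en <- GenomicRanges::end(features)[f]
    minus <- as.character(GenomicRanges::strand(features))[f] == "-"
    ch <- as.character(GenomicRanges::seqnames(features))[f]
    anchorPos <- if ((anchor == "5prime") != minus) st else en
    for (r in which(cyt$chrom == ch)) {
      off <- if (minus) anchorPos - cyt$pos[r] else cyt$pos[r] - anchorPos
      if (off < -flank || off >= flank) next
      tot <- cyt$meth[r] + cyt$unmeth[r]
      if (tot == 0) next
      b <- (off + flank) %/% bin + 1L
      accM[b] <- accM[b] + cyt$meth[r]
      accT[b] <- accT[b] + tot
      accR[b] <- accR[b] + cyt$meth[r] / tot
      accN[b] <- accN[b] + 1
    }
  }
  if (weighted) ifelse(accT > 0, accM / accT, NA_real_)
  else ifelse(accN > 0, accR / accN, NA_real_)
}

# Scaled TE profile, position by position.
oracleTeProfile <- function(coverage, tes, flank, bodyBins) {
  nBins <- flank + bodyBins + flank
  tot <- nT <- numeric(nBins)
  for (f in seq_along(tes)) {
    st <- GenomicRanges::start(tes)[f]
    en <- GenomicRanges::end(tes)[f]
    L <- en - st + 1L
    minus <- as.character(GenomicRanges::strand(tes))[f] == "-"
    ch <- as.character(GenomicRanges::seqnames(tes))[f]
    vals <- rep(list(numeric(0)), nBins)
    sub <- coverage[coverage$chrom == ch, ]
    gs <- (st - flank):(en + flank)
    vv <- sub$value[match(gs, sub$pos)]
    vv[is.na(vv)] <- 0
    for (k in seq_along(gs)) {
      g <- gs[k]
      off <- if (minus) en - g else g - st
      b <- if (off < 0) off + flank + 1L
      else if (off >= L) flank + bodyBins + (off - L) + 1L
      else flank + min(floor(off * bodyBins / L), bodyBins - 1) + 1L
      vals[[b]] <- c(vals[[b]], vv[k])
    }
    for (b in seq_len(nBins)) {
      if (length(vals[[b]])) {
        tot[b] <- tot[b] + mean(vals[[b]])
        nT[b] <- nT[b] + 1
      }
    }
  }
  ifelse(nT > 0, tot / nT, NA_real_)
}

# Build a SmoothedMethylome directly from per-cytosine smoothed counts.
makeSmoothed <- function(genotype, chrom, context, pos, meth, unmeth) {
  tr <- SmoothedTrack(genotype, chrom, context, pos, meth, unmeth)
  m <- new("SmoothedMethylome", genotype = genotype,
           tracks = stats::setNames(list(tr), paste0(chrom, ":", context)))
  m
}
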