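---
title: "An error-corrected, constraint-respecting codec for DNA data storage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An error-corrected, constraint-respecting codec for DNA data storage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligocodec)
```

## The storage model

A file stored in DNA passes through synthesis, storage, PCR, and
sequencing, each of which can substitute, delete, or insert bases.
Second-generation platforms err at roughly 1% per base; substitutions are
the most common type. On top of that, some sequences are simply bad
citizens: skewed GC content hampers PCR, homopolymer runs raise read/write
error rates, `GAATTC` is cleaved by EcoRI during in-vivo storage, and `GGC`
inflates Illumina error rates. A practical codec therefore has to solve
two problems at once — correct indels as well as substitutions, and only
ever emit sequences that respect the biochemical constraints.

`oligocodec` composes four independently testable layers:

1. a pluggable lossless **compression** stage,
2. a **packetizer** that segments the bitstream into indexed blocks,
3. a systematic **Levenshtein-code** layer that protects each block against
   one substitution, deletion, or insertion,
4. a **constrained transcoder** that turns code bits into DNA which
   satisfies the constraints *structurally*, not by rejection sampling.

## The Levenshtein code layer

A length-$m$ word $x$ belongs to $L(m, r, U)$ when
$\sum_{k=1}^{m} k\,x_k \equiv r \pmod U$. We fix $r = 0$ and $U = 2m$, the
regime in which the code corrects any single substitution, deletion, or
insertion. The geometry follows from the message length $l$ via
$l = m' - \lceil \log_2 m' \rceil - 1$, $m = \min m'$; check bits sit at
the power-of-two positions plus position $m$ (the last position is always
a check bit; the second-to-last always a message bit).

```{r geometry}
p <- lc_params(12)
p
```

**Parity assignment.** The check bits must contribute
$s = (U - S_{\mathrm{msg}}) \bmod U$ to the weighted sum, where
$S_{\mathrm{msg}}$ is the message-only sum. We decompose $s$ greedily over
the parity weights $\{m\} \cup \{2^i \le m\}$, largest first. This is total
on $[0, 2m)$: if $s \ge m$ the remainder $s - m \le m - 1$ has an ordinary
binary expansion over the remaining powers of two, and if $s < m$ the
binary expansion applies directly. The test suite verifies totality
exhaustively for every geometry up to $m = 64$. Note that the greedy
*positional* decomposition is not the same as writing $s$ in binary across
the check-bit slots; for the 12-bit example message the required $s = 9$
sets positions $8$ and $1$, not a binary-literal bit pattern.

```{r encode}
cw <- lc_encode("101000011110", p)
bits_to_string(cw)
lc_weighted_sum(cw)  # 72 = 2U, congruent to 0 (mod 36)
```

**Decoding.** At length $m$ the syndrome $d = S \bmod 2m$ localises a
substitution: $d \le m$ with a received 1 at position $d$ is a $0\to1$
flip there; $d \ge m$ with a received 0 at position $2m - d$ is a $1\to0$
flip; at $d = m$ the received bit at position $m$ disambiguates the
direction. For indels we deliberately use exhaustive candidate enumeration
(all $2m$ reinsertions, or all $m+1$ deletions, in $O(m)$ total via suffix
sums) rather than the closed-form decoder: at block sizes of tens of bits
the cost is negligible, the enumeration is its own correctness oracle, and
ties are reported as `ambiguous` rather than guessed. Inputs whose length
differs from $m$ by more than one are out of the code's design scope and
return `uncorrectable`.

## The constrained transcoder

Three bits map to two bases: `000→TC, 001→TG, 010→AC, 011→AG, 100→CT,
101→CA, 110→GT, 111→GA`. Each pair contains exactly one strong (G/C) and
one weak (A/T) base, so three constraints hold *by construction*:

* **GC content** is exactly 50% in every pair-aligned window (we interpret
  "local" GC as pair-aligned windows; the audit reports whole-sequence GC,
  and the per-pair property is enforced structurally);
* **homopolymers** never exceed 2 nt — a run of 3 would need a pair `XX`,
  which the codebook excludes, or equal bases across a pair boundary, which
  the test suite rules out by exhausting all $8^3$ three-pair windows;
* the motifs **GAATTC** and **GGC** cannot occur, by the same exhaustion
  (both motifs span at most three pairs).

```{r mapper}
bits_to_dna(cw)
audit_sequence(bits_to_dna(cw))
```

The mapping's known blind spot: a substitution between complementary bases
*within* A/T or within G/C (`T↔A`, `C↔G`) converts a valid pair into
another valid pair and flips exactly one code bit — which the LC layer then
corrects. Any other substitution produces a dinucleotide outside the
codebook. We decode such invalid pairs to placeholder bits plus an
*erasure* record, and resolve them by enumerating replacement pairs
(Hamming-distance-1 valid pairs first, then all eight) and demanding a
unique zero-syndrome completion; ambiguity fails the block rather than
guessing. Motif scanning is single-strand by default (encoder outputs are
what we audit); `both_strands = TRUE` adds the reverse complement.

## Packets, indexing, and the decoder's search

Each oligo carries `[index | payload slice | zero padding]`, cut into
$l$-bit messages and encoded block by block. Design choices where the
format was genuinely open:

* the index occupies the leading message bits, so it enjoys the same error
  protection as the payload and blocks stay uniform;
* the index width defaults to $\lceil \log_2(\text{oligo count}) \rceil$
  (computed by fixed-point iteration, since capacity depends on the width)
  and is recorded in the sidecar;
* padding is zeros; the true payload bit length lives in the sidecar;
* an MD5 checksum of the payload bitstream operationalises "accept this
  reconstruction": reassembly only succeeds if the checksum matches.

A requested oligo length is rounded **down** to a whole number of LC
blocks: one $m = 18$ block occupies 12 nt, so the default request of
208 nt yields 17 blocks = 204 nt. We also require $m \equiv 0 \pmod 3$ so
block boundaries align with base pairs — that alignment is what lets the
decoder localise an indel to one block. Geometries that violate it are
rejected at configuration time with a pointer to ones that work
($l \in \{2, 7, 12, 15, \dots\}$).

Reads are decoded with a per-block cursor. A nominal-size chunk is
accepted if it is a codeword, carries one correctable substitution, or has
a uniquely resolvable erasure. When the read's remaining length disagrees
with the remaining block count, the decoder first tries a strict
exact-codeword match at nominal size, then repairs the off-by-one chunk by
enumerating single-base reinsertions/deletions (accepting only a unique
strictly-valid repair), and finally falls back to a lenient nominal-size
decode. Reads that still fail, or that leave unconsumed bases, are
discarded as invalid — a read with more than one indel per block is beyond
the design scope and is dropped, not heuristically repaired. A rare
failure mode remains: a chunk overlapping an indel can masquerade as a
correctable codeword and silently misalign the rest of the read. Majority
voting across `reads_per_oligo` candidates and the payload checksum are
the backstops; the end-to-end tests exercise exactly this interplay.

## The channel simulator

Errors are i.i.d. per base at rate $p$, with type drawn from a
substitution/deletion/insertion mix of $(0.5, 0.25, 0.25)$ by default —
substitutions account for half of all errors, reflecting their dominance
on common platforms. Substituted bases are uniform over the three
alternatives; insertions place a uniform base after the errant position
(both conventions are ours; no published profile pins them down). The
generator emulates rate and type mix only — real channels have
position- and motif-dependent error profiles and whole-oligo dropout,
which we deliberately do not model, so a clean pass here does not certify
performance on any particular platform. Every run is reproducible from
the integer seed; a fixed-count mode (`round(p * n)` errors per read)
supports variance-matched comparisons.

## Compression and metrics

The compression stage is an interface, not a commitment: `passthrough`
and a gzip codec (framed with a header holding the original length and an
MD5 of the deflated body, so corrupted streams fail fast instead of
inflating garbage). Learned image compressors can reach densities well
above 2 bits/nt; plugging one in is a matter of feeding its bitstream to
`build_oligos()`. Net information density is original-file bits divided
by total synthesized bases, with 1 KB = 1024 bytes — the convention under
which the published pool geometries and densities are mutually consistent.
SSIM is the standard single-scale formulation (Gaussian window 11,
$\sigma = 1.5$, $K_1 = 0.01$, $K_2 = 0.03$, dynamic range from the data),
computed on the channel mean for colour images (Rec.601 luma behind a
flag); no installed package provides SSIM, so the metrics layer implements
it and the tests cross-check it against a naive sliding-window evaluation
and the closed form for constant images.

## Numerical choices and problem sizes

Degenerate inputs are rejected early: $l = 0$ messages (the geometry
equations degenerate), empty payloads, empty pools, odd-length DNA at the
transcoder (a probable indel, handled upstream). Decoder ties anywhere —
indel candidates, erasure completions — surface as failures, never silent
choices. The test suite proves the single-error property exhaustively at
the default geometry (all 4096 messages $\times$ all 74 single errors at
$m = 18$) and checks deletion-ball disjointness by enumeration at $m = 8$;
end-to-end runs use pools of tens of oligos at error rates 0.1–2% with 10
reads per oligo, sizes chosen to exercise every correction path while
keeping the suite quick to run.

## Limitations

One error per LC block is the design point; error rates that routinely put
two errors in an 18-bit block need shorter blocks or an outer code. There
is no inter-oligo redundancy: a lost oligo (no valid read) is a reported
recovery failure, by design. The 2-bit/nt ceiling means high densities
come entirely from the compression stage, and the bundled gzip codec is a
stand-in for stronger, domain-specific compressors.
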