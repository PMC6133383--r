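"""Exact-rational oracle for the two-sided binomial sign test at p0 = 1/2.

Computes p(k, n) = min(1, 2 * sum_{i=0..min(k, n-k)} C(n, i) / 2^n) with
arbitrary-precision integer arithmetic (no floating point until the final,
correctly rounded conversion), for every 0 <= k <= n, n <= NMAX.

Usage: python exact_sign_test.py [NMAX]
Output: tab-separated lines "n k p" on stdout.
"""
import sys
from fractions import Fraction
from math import comb


def main(nmax: int) -> None:
    out = sys.stdout
    for n in range(1, nmax + 1):
        denom = 1 << n
        # cumulative lower-tail sums up to n//2
        cum = []
        s = 0
        for i in range(n // 2 + 1):
            s += comb(n, i)
            cum.append(s)
        for k in range(n + 1):
            kk = min(k, n - k)
            p = Fraction(2 * cum[kk], denom)
            if p > 1:
                p = Fraction(1)
            out.write(f"{n}\t{k}\t{float(p)!r}\n")


if __name__ == "__main__":
    main(int(sys.argv[1]) if len(sys.argv) > 1 else 300)
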