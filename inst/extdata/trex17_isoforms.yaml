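# Defined splice isoforms of the human lncRNA T-REX17 (hg19 browser
# coordinates, 1-based). Junctions are canonicalized left < right; the
# higher coordinate (chr8:55,140,806) is the 5' end of exon 1 on the minus
# strand. List order is classification priority. Any split read matching
# neither definition is "sloppy".
isoforms:
  - name: "Ex1+2"
    junctions:
      - left: 55125601
        right: 55140806
  - name: "Ex1+3"
    junctions:
      - left: 55123254
        right: 55140806
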