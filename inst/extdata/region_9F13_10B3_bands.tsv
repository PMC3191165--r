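name	type	start	end
9F13/10A1-2	IB	10792800	10793400
10A1-2	B	10793401	10984199
10A1-2/10A3	IB	10984200	10985600
10A3	B	10985601	11002399
10A3/10A4-5	IB	11002400	11004400
10A4-5	B	11004401	11017399
10A4-5/10A6	IB	11017400	11020400
10A6	B	11020401	11022399
10A6/10A7	IB	11022400	11024000
10A7	B	11024001	11029999
10A7/10A8-9	IB	11030000	11033000
10A8-9	B	11033001	11041199
10A8-9/10A10	IB	11041200	11044000
10A10-11	B	11044001	11048599
10A10-11/10B1-2	IB	11048600	11050000
10B1-2	B	11050001	11217799
10B1-2/10B3	IB	11217800	11220400
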