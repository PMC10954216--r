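individual_id	entheses	ovalization	lesion	platymeric	vertebral	trauma
032	+	?	+	+	+	-
034	+	?	+	+	-	-
064	+	+	+	+	+	+
081	+	?	?	+	+	-
082	+	?	+	+	-	-
092	-	?	+	?	+	+
103	+	?	+	?	-	+
116	+	?	?	+	+	+
118	+	+	+	+	+	-
130	+	?	+	+	?	-
135	+	?	+	-	+	-
148	+	-	+	-	+	-
153	+	+	+	-	+	+
161	+	+	-	+	+	-
164	+	?	+	-	+	-
166	+	?	?	+	?	+
170	+	?	+	+	?	?
174	+	?	+	+	?	-
177	+	?	+	+	?	-
186	+	?	+	+	?	?
198	?	-	+	?	+	+
209	+	+	+	-	+	+
213	+	+	+	+	+	-
215	+	+	-	+	+	-
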